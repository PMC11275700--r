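#' Simulate V2-like neural responses to a stimulus set
#'
#' Generates a neurons x images response matrix aligned to a `stimulus_set`,
#' emulating the shape and metadata of classic V2 texture-modulation
#' recordings (103 neurons, 450 images with the default stimulus design).
#' Two generator modes:
#' \describe{
#' \item{metadata}{`response = baseline_n + gain_n * 1[texture] * m[n, family]
#'   + noise`, rectified at zero. The noise-free modulation index is analytic:
#'   with drive `g = gain_n * m[n, i]`, `Rmod = g / (2 b + g)`.}
#' \item{feature}{`response = softplus(w_n . features) + noise`, for
#'   partial-least-squares recovery tests; the generating weights are stored
#'   as ground truth.}
#' }
#'
#' @param stimuli a `stimulus_set`.
#' @param n_neurons number of simulated neurons (default 103).
#' @param mode `"metadata"` or `"feature"`.
#' @param baseline_range,gain_range uniform ranges for per-neuron baseline
#'   firing rate and texture gain (metadata mode; spikes/s).
#' @param family_strength_range uniform range of per-family modulation
#'   strength; per-neuron sensitivity is uniform on (0.2, 1).
#' @param noise_sd Gaussian response noise (spikes/s).
#' @param feature_basis images x dims feature matrix (feature mode; required
#'   there).
#' @param rng_seed integer seed.
#' @return Object of class `neural_dataset`: list with `responses`
#'   (neurons x images, non-negative), `meta` (the stimulus metadata),
#'   `ground_truth` (mode-specific parameters), `mode`.
#' @export
simulate_v2_neurons <- function(stimuli, n_neurons = 103,
                                mode = c("metadata", "feature"),
                                baseline_range = c(5, 15),
                                gain_range = c(2, 10),
                                family_strength_range = c(0.2, 1),
                                noise_sd = 1,
                                feature_basis = NULL, rng_seed = 1L) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  mode <- match.arg(mode)
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (baseline_range[1] <= 0) stopf("baselines must be positive")
  meta <- stimuli$meta
  n_img <- nrow(meta)
  with_seed(rng_seed, {
    if (mode == "metadata") {
      fams <- sort(unique(meta$family_id))
      baseline <- stats::runif(n_neurons, baseline_range[1], baseline_range[2])
      gain <- stats::runif(n_neurons, gain_range[1], gain_range[2])
      fam_strength <- stats::runif(length(fams), family_strength_range[1],
                                   family_strength_range[2])
      sens <- stats::runif(n_neurons, 0.2, 1)
      m <- outer(sens, fam_strength)             # neurons x families
      drive <- matrix(baseline, n_neurons, n_img)
      is_tex <- meta$condition == "texture"
      fam_col <- match(meta$family_id, fams)
      drive[, is_tex] <- drive[, is_tex] +
        (gain * m[, fam_col[is_tex], drop = FALSE])
      resp <- drive
      if (noise_sd > 0) {
        resp <- resp + matrix(stats::rnorm(n_neurons * n_img, 0, noise_sd),
                              n_neurons, n_img)
      }
      resp <- pmax(resp, 0)
      gt <- list(baseline = baseline, gain = gain, modulation = m,
                 rmod_true = (gain * m) / (2 * baseline + gain * m))
    } else {
      if (is.null(feature_basis)) stopf("feature mode requires feature_basis")
      if (nrow(feature_basis) != n_img) {
        stopf("feature_basis rows (%d) must align to stimuli (%d)",
              nrow(feature_basis), n_img)
      }
      f <- scale(feature_basis)
      f[is.na(f)] <- 0
      w <- matrix(stats::rnorm(n_neurons * ncol(f)), n_neurons, ncol(f))
      drive <- w %*% t(f)
      drive <- drive / pmax(apply(drive, 1, stats::sd), 1e-12)  # unit spread
      # offset keeps neurons in the near-linear regime of the softplus, so a
      # linear readout can recover them in the noise-free limit
      drive <- 3 + drive
      resp <- log1p(exp(drive))                    # softplus
      if (noise_sd > 0) {
        resp <- resp + matrix(stats::rnorm(n_neurons * n_img, 0, noise_sd),
                              n_neurons, n_img)
      }
      resp <- pmax(resp, 0)
      gt <- list(weights = w)
    }
    structure(list(responses = resp, meta = meta, ground_truth = gt, mode = mode),
              class = "neural_dataset")
  })
}

#' Texture modulation index table
#'
#' For each neuron n and texture family i, averages responses across image
#' samples within the texture and noise conditions and computes
#' `Rmod[n, i] = (tex - noise) / (tex + noise)`, together with the
#' per-neuron average over families and the per-family average over neurons.
#' Entries with `tex + noise = 0` are undefined: they are set to `NA`,
#' excluded from the averages, and counted in attribute `n_undefined`.
#'
#' @param data a `neural_dataset` (or a list with `responses` and `meta`).
#' @return Object of class `modulation_table`: list with `rmod`
#'   (neurons x families), `per_neuron`, `per_family`, `tex`, `noise`.
#' @export
modulation_index <- function(data) {
  resp <- data$responses
  meta <- data$meta
  if (ncol(resp) != nrow(meta)) stopf("responses and metadata are misaligned")
  fams <- sort(unique(meta$family_id))
  n_neurons <- nrow(resp)
  tex <- noise <- matrix(NA_real_, n_neurons, length(fams))
  for (fi in seq_along(fams)) {
    ti <- meta$family_id == fams[fi] & meta$condition == "texture"
    ni <- meta$family_id == fams[fi] & meta$condition == "noise"
    if (!any(ti) || !any(ni)) {
      stopf("family %s lacks one of the conditions", fams[fi])
    }
    tex[, fi] <- rowMeans(resp[, ti, drop = FALSE])
    noise[, fi] <- rowMeans(resp[, ni, drop = FALSE])
  }
  denom <- tex + noise
  rmod <- (tex - noise) / denom
  rmod[denom == 0] <- NA_real_
  out <- structure(list(rmod = rmod,
                        per_neuron = rowMeans(rmod, na.rm = TRUE),
                        per_family = colMeans(rmod, na.rm = TRUE),
                        tex = tex, noise = noise,
                        families = fams),
                   class = "modulation_table")
  attr(out, "n_undefined") <- sum(denom == 0)
  out
}

# ---- partial least squares (SIMPLS) --------------------------------------

# Multi-response PLS regression, SIMPLS algorithm (de Jong 1993). X and Y are
# centered internally; returns coefficients on the original scale.
simpls_fit <- function(X, Y, ncomp) {
  n <- nrow(X)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Y, 2, ym)
  S <- crossprod(Xc, Yc)                          # p x q
  p <- ncol(X); q <- ncol(Y)
  R <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp); V <- matrix(0, p, ncomp)
  s1_init <- NA_real_
  for (a in seq_len(ncomp)) {
    # dominant right singular vector of S via the q x q Gram matrix
    StS <- crossprod(S)
    ev <- eigen(StS, symmetric = TRUE)
    s1 <- sqrt(max(ev$values[1], 0))
    if (a == 1) s1_init <- s1
    # stop once the deflated cross-covariance is numerically exhausted
    # (components beyond the effective rank only amplify round-off)
    if (s1 < 1e-8 * s1_init) {
      R <- R[, seq_len(a - 1), drop = FALSE]
      Q <- Q[, seq_len(a - 1), drop = FALSE]
      break
    }
    qv <- ev$vectors[, 1]
    r <- S %*% qv
    t_sc <- Xc %*% r
    t_sc <- t_sc - mean(t_sc)
    normt <- sqrt(sum(t_sc^2))
    if (normt < 1e-12) { R <- R[, seq_len(a - 1), drop = FALSE]
                         Q <- Q[, seq_len(a - 1), drop = FALSE]; break }
    t_sc <- t_sc / normt; r <- r / normt
    pl <- crossprod(Xc, t_sc)
    ql <- crossprod(Yc, t_sc)
    v <- pl
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pl)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- ql; V[, a] <- v
  }
  B <- R %*% t(Q)
  list(coef = B, x_mean = xm, y_mean = ym, ncomp = ncol(R))
}

simpls_predict <- function(fit, Xnew) {
  sweep(sweep(Xnew, 2, fit$x_mean) %*% fit$coef, 2, fit$y_mean, "+")
}

#' Cross-validated PLS neural predictivity
#'
#' Fits a partial-least-squares regression from model features to all
#' neurons jointly, per cross-validation fold, and scores each neuron on
#' held-out images by the squared Pearson correlation between predicted and
#' observed responses. Degenerate (constant) predicted or observed vectors
#' score 0 for that neuron/fold. Reports the per-neuron mean over folds and
#' the population median.
#'
#' @param features images x dims numeric matrix, row-aligned to `responses`.
#' @param responses a `neural_dataset` or a neurons x images matrix.
#' @param n_components PLS components (default 25; reduced if it exceeds
#'   the fold training size or feature dimensionality).
#' @param n_folds cross-validation folds (default 10).
#' @param rng_seed integer seed for the fold split.
#' @return Object of class `pls_predictivity`: list with `per_neuron`
#'   (mean explained variance per neuron), `per_fold` (neurons x folds),
#'   `median_ev`, `n_components`, `folds`.
#' @export
fit_pls_predictivity <- function(features, responses, n_components = 25,
                                 n_folds = 10, rng_seed = 1L) {
  resp <- if (inherits(responses, "neural_dataset")) responses$responses else responses
  n_img <- ncol(resp)
  if (nrow(features) != n_img) {
    stopf("features rows (%d) must equal response columns (%d)",
          nrow(features), n_img)
  }
  keep <- which(apply(features, 2, stats::sd) > 0)
  features <- features[, keep, drop = FALSE]
  with_seed(rng_seed, {
    fold_id <- sample(rep(seq_len(n_folds), length.out = n_img))
    n_neurons <- nrow(resp)
    per_fold <- matrix(NA_real_, n_neurons, n_folds)
    for (f in seq_len(n_folds)) {
      te <- which(fold_id == f); tr <- which(fold_id != f)
      nc <- min(n_components, length(tr) - 1, ncol(features))
      fit <- simpls_fit(features[tr, , drop = FALSE], t(resp[, tr, drop = FALSE]), nc)
      pred <- simpls_predict(fit, features[te, , drop = FALSE])  # img x neurons
      obs <- t(resp[, te, drop = FALSE])
      for (nn in seq_len(n_neurons)) {
        if (stats::sd(pred[, nn]) == 0 || stats::sd(obs[, nn]) == 0) {
          per_fold[nn, f] <- 0
        } else {
          per_fold[nn, f] <- stats::cor(pred[, nn], obs[, nn])^2
        }
      }
    }
    per_neuron <- rowMeans(per_fold)
    structure(list(per_neuron = per_neuron, per_fold = per_fold,
                   median_ev = stats::median(per_neuron),
                   n_components = n_components, folds = fold_id),
              class = "pls_predictivity")
  })
}

#' @export
print.pls_predictivity <- function(x, ...) {
  cat(sprintf("PLS predictivity: %d neurons, %d folds, median explained variance %.3f\n",
              length(x$per_neuron), ncol(x$per_fold), x$median_ev))
  invisible(x)
}

#' Select the best model layer on a validation split
#'
#' Given per-layer predictivity results computed on a validation split,
#' returns the layer with the highest median explained variance; the final
#' reported score must then come from an untouched test split. Ties go to
#' the lowest layer index.
#'
#' @param results named or unnamed list of `pls_predictivity` objects, one
#'   per layer, in layer order.
#' @return Integer index of the selected layer.
#' @export
select_best_layer <- function(results) {
  if (!length(results)) stopf("need at least one layer result")
  meds <- vapply(results, function(r) r$median_ev, numeric(1))
  which.max(meds)  # which.max returns the first (lowest) index on ties
}

#' Partition neurons into V1-like and V2-like quartiles
#'
#' Sorts neurons by how well a baseline V1 model explains them; the top
#' quartile (best explained) is labelled V1-like and the bottom quartile
#' V2-like. Quartile size is `ceiling(N / 4)` (103 neurons give 26 per
#' subset). Ties at a boundary are resolved by stable sort order.
#'
#' @param baseline_scores numeric vector of per-neuron explained variance
#'   under the baseline model.
#' @return List with integer id vectors `v1_like` and `v2_like`.
#' @export
partition_neurons <- function(baseline_scores) {
  n <- length(baseline_scores)
  if (!n) stopf("need at least one score")
  k <- ceiling(n / 4)
  ord <- order(baseline_scores, decreasing = TRUE)  # stable radix order
  list(v1_like = sort(ord[seq_len(k)]),
       v2_like = sort(ord[(n - k + 1):n]))
}

#' Quantile-quantile comparison of modulation distributions
#'
#' Computes empirical quantiles of two samples at matched probability points
#' and the maximum absolute quantile gap, the numeric summary of a Q-Q plot.
#'
#' @param model,reference numeric vectors (e.g. per-neuron modulation
#'   indices); NAs dropped.
#' @param n_quantiles number of probability points.
#' @return List with `probs`, `model_q`, `reference_q`, `max_deviation`.
#' @export
qq_compare <- function(model, reference, n_quantiles = 21) {
  model <- model[!is.na(model)]; reference <- reference[!is.na(reference)]
  if (!length(model) || !length(reference)) stopf("samples must be non-empty")
  probs <- stats::ppoints(n_quantiles)
  mq <- stats::quantile(model, probs, names = FALSE)
  rq <- stats::quantile(reference, probs, names = FALSE)
  list(probs = probs, model_q = mq, reference_q = rq,
       max_deviation = max(abs(mq - rq)))
}

spearman_rho <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Family-rank comparison of texture modulation
#'
#' Ranks the per-family modulation indices of model and reference neurons
#' (1 = lowest-modulation family) and reports the Spearman rank correlation.
#' When a competitor model and the per-neuron tables are supplied, the
#' significance of the difference between the two models' correlations with
#' the reference is assessed by paired bootstrap resampling of neurons
#' (family means recomputed per resample; two-sided).
#'
#' @param model,reference numeric per-family modulation vectors (equal
#'   length, default design 15 families).
#' @param competitor optional per-family vector for a competing model.
#' @param model_table,competitor_table,reference_table optional
#'   neurons x families `Rmod` matrices (or `modulation_table` objects) used
#'   for the bootstrap.
#' @param n_bootstrap bootstrap resamples (default 10000).
#' @param rng_seed integer seed.
#' @return List with `rho`, `ranks` (data.frame of paired ranks),
#'   `rho_competitor`, `delta_rho`, `p_value`.
#' @export
family_rank_compare <- function(model, reference, competitor = NULL,
                                model_table = NULL, competitor_table = NULL,
                                reference_table = NULL,
                                n_bootstrap = 10000, rng_seed = 1L) {
  if (length(model) != length(reference)) stopf("family vectors must have equal length")
  rho <- spearman_rho(model, reference)
  ranks <- data.frame(family = seq_along(model),
                      model_rank = rank(model),
                      reference_rank = rank(reference))
  rho_c <- if (!is.null(competitor)) spearman_rho(competitor, reference) else NA_real_
  p_value <- NA_real_
  get_tab <- function(x) if (inherits(x, "modulation_table")) x$rmod else x
  mt <- get_tab(model_table); ct <- get_tab(competitor_table); rt <- get_tab(reference_table)
  if (!is.null(mt) && !is.null(ct) && !is.null(rt) && !is.na(rho_c)) {
    obs_delta <- rho - rho_c
    deltas <- with_seed(rng_seed, {
      vapply(seq_len(n_bootstrap), function(b) {
        idx_m <- sample.int(nrow(mt), replace = TRUE)
        idx_c <- sample.int(nrow(ct), replace = TRUE)
        idx_r <- sample.int(nrow(rt), replace = TRUE)
        fm <- colMeans(mt[idx_m, , drop = FALSE], na.rm = TRUE)
        fc <- colMeans(ct[idx_c, , drop = FALSE], na.rm = TRUE)
        fr <- colMeans(rt[idx_r, , drop = FALSE], na.rm = TRUE)
        spearman_rho(fm, fr) - spearman_rho(fc, fr)
      }, numeric(1))
    })
    deltas <- deltas[!is.na(deltas)]
    # two-sided: how often the bootstrap difference crosses zero
    p_value <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
    p_value <- min(1, max(p_value, 1 / length(deltas)))
  }
  list(rho = rho, ranks = ranks, rho_competitor = rho_c,
       delta_rho = if (is.na(rho_c)) NA_real_ else rho - rho_c,
       p_value = p_value)
}

#' Relative improvement in percent
#'
#' `100 * (candidate - baseline) / baseline`; e.g. a behavioral-consistency
#' score of 0.211 over a baseline of 0.165 is a 27.9% (~28%) relative
#' improvement.
#'
#' @param candidate,baseline numeric scores; `baseline` must be positive.
#' @return Percent relative improvement.
#' @export
relative_improvement <- function(candidate, baseline) {
  if (baseline <= 0) stopf("baseline must be positive")
  100 * (candidate - baseline) / baseline
}
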