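#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param weight_decay L2 penalty added to gradients (default 0, i.e. none).
#' @param batch_size images per batch.
#' @param max_epochs maximum training epochs.
#' @param val_fraction fraction of the corpus held out for the validation
#'   loss used by early stopping (0 < f < 1).
#' @param stop_threshold minimum relative improvement of the best summed
#'   validation loss that counts as progress.
#' @param stop_patience number of consecutive non-improving validation
#'   evaluations tolerated before stopping.
#' @param seed master seed for the run (data split, view sampling,
#'   initialization of auxiliary parameters).
#' @param loss loss family per layer: `"barlow"`, `"simclr"` or `"simsiam"`;
#'   length 1 (shared) or one per layer.
#' @param lambda Barlow off-diagonal weight.
#' @param center center features before the cross-correlation (see
#'   [cross_correlation()]).
#' @param temperature SimCLR temperature.
#' @param mode `"interleaved"` (both layers updated every batch, the default)
#'   or `"sequential"` (layer 1 trained to its stopping point first).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0,
                         batch_size = 32, max_epochs = 20, val_fraction = 0.1,
                         stop_threshold = 1e-3, stop_patience = 5, seed = 1L,
                         loss = "barlow", lambda = 0.005, center = FALSE,
                         temperature = 0.1,
                         mode = c("interleaved", "sequential")) {
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (val_fraction <= 0 || val_fraction >= 1) stopf("val_fraction must be in (0, 1)")
  if (!all(loss %in% c("barlow", "simclr", "simsiam"))) {
    stopf("loss must be one of barlow, simclr, simsiam")
  }
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction, stop_threshold = stop_threshold,
                 stop_patience = as.integer(stop_patience),
                 seed = as.integer(seed), loss = loss, lambda = lambda,
                 center = center, temperature = temperature,
                 mode = match.arg(mode)),
            class = "train_config")
}

#' Early-stopping decision on a validation-loss sequence
#'
#' Scans summed validation losses in order; an evaluation counts as progress
#' when it improves the best loss seen so far by more than `stop_threshold`
#' (relative). After `stop_patience` consecutive evaluations without
#' progress, training stops.
#'
#' @param val_losses numeric vector of summed validation losses, one per
#'   evaluation, in order.
#' @param stop_threshold,stop_patience see [train_config()].
#' @return List with `stop` (logical) and `stop_epoch` (index of the
#'   evaluation at which the decision fires, or `NA`).
#' @export
early_stop <- function(val_losses, stop_threshold = 1e-3, stop_patience = 5) {
  if (length(val_losses) < 1) stopf("need at least one validation record")
  best <- val_losses[1]
  wait <- 0L
  for (i in seq_along(val_losses)[-1]) {
    rel <- (best - val_losses[i]) / abs(best)
    if (is.finite(rel) && rel > stop_threshold) {
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= stop_patience) return(list(stop = TRUE, stop_epoch = i))
    }
    if (val_losses[i] < best) best <- val_losses[i]
  }
  list(stop = FALSE, stop_epoch = NA_integer_)
}

# ---- parameter packing helpers -------------------------------------------

layer_params <- function(enc, layer, predictor = NULL) {
  st <- if (layer == 1) enc$stage1 else enc$stage2
  pj <- if (layer == 1) enc$proj1 else enc$proj2
  p <- list(W = st$W, b = st$b, gamma = st$bn$gamma, beta = st$bn$beta,
            pW1 = pj$W1, pb1 = pj$b1, pW2 = pj$W2, pb2 = pj$b2)
  if (!is.null(predictor) && !isTRUE(predictor$identity)) {
    p <- c(p, list(qW1 = predictor$W1, qb1 = predictor$b1,
                   qW2 = predictor$W2, qb2 = predictor$b2))
  }
  p
}

put_layer_params <- function(enc, layer, p, predictor = NULL) {
  nm <- if (layer == 1) "stage1" else "stage2"
  pj <- if (layer == 1) "proj1" else "proj2"
  enc[[nm]]$W <- p$W; enc[[nm]]$b <- p$b
  enc[[nm]]$bn$gamma <- p$gamma; enc[[nm]]$bn$beta <- p$beta
  enc[[pj]]$W1 <- p$pW1; enc[[pj]]$b1 <- p$pb1
  enc[[pj]]$W2 <- p$pW2; enc[[pj]]$b2 <- p$pb2
  if (!is.null(predictor) && !isTRUE(predictor$identity)) {
    predictor$W1 <- p$qW1; predictor$b1 <- p$qb1
    predictor$W2 <- p$qW2; predictor$b2 <- p$qb2
  }
  list(enc = enc, predictor = predictor)
}

# stack per-image view pairs into (v, v, 1, B) arrays
make_view_batch <- function(images, idx, spec) {
  b <- length(idx)
  v <- spec$view_size
  A <- array(0, c(v, v, 1, b)); B <- array(0, c(v, v, 1, b))
  for (k in seq_len(b)) {
    vp <- make_view_pair(images[, , idx[k]], spec)
    A[, , 1, k] <- vp$A; B[, , 1, k] <- vp$B
  }
  list(A = A, B = B)
}

loss_grad_dispatch <- function(zA, zB, loss, config, predictor) {
  switch(loss,
    barlow = barlow_grad(zA, zB, lambda = config$lambda, center = config$center),
    simclr = sample_contrastive_grad(zA, zB, temperature = config$temperature),
    simsiam = noncontrastive_grad(zA, zB, predictor))
}

# forward + backward for one layer on one view-pair batch. Gradient isolation
# is structural: the layer-2 pass treats stage 1 as a frozen feature
# extractor (its batch-norm running statistics are not updated and no
# backward pass reaches it).
layer_pass <- function(enc, layer, vb, config, loss, predictor,
                       compute_grads = TRUE, training = TRUE) {
  fwd_one <- function(x) {
    s1 <- stage_forward_one(enc$stage1, x, training = training)
    if (layer == 1) {
      list(fm = s1$y, stage_cache = s1$cache, stage_out = s1$stage)
    } else {
      s2 <- stage_forward_one(enc$stage2, s1$y, training = training)
      list(fm = s2$y, stage_cache = s2$cache, stage_out = s2$stage)
    }
  }
  proj <- if (layer == 1) enc$proj1 else enc$proj2
  fA <- fwd_one(vb$A)
  fB <- fwd_one(vb$B)
  # running-statistic updates apply only to the stage this loss trains
  if (training) {
    if (layer == 1) enc$stage1 <- fB$stage_out else enc$stage2 <- fB$stage_out
  }
  pA <- project_and_pool_full(fA$fm, proj)
  pB <- project_and_pool_full(fB$fm, proj)
  lg <- loss_grad_dispatch(pA$z, pB$z, loss, config, predictor)
  if (!is.finite(lg$loss)) {
    stopf("non-finite layer-%d loss (%s); aborting", layer, loss)
  }
  out <- list(loss = lg$loss, enc = enc)
  if (compute_grads) {
    st <- if (layer == 1) enc$stage1 else enc$stage2
    bpA <- project_and_pool_backward(lg$dzA, proj, pA$cache)
    bpB <- project_and_pool_backward(lg$dzB, proj, pB$cache)
    sgA <- stage_backward_one(st, bpA$dx, fA$stage_cache)
    sgB <- stage_backward_one(st, bpB$dx, fB$stage_cache)
    g <- list(W = sgA$dW + sgB$dW, b = sgA$db + sgB$db,
              gamma = sgA$dgamma + sgB$dgamma, beta = sgA$dbeta + sgB$dbeta,
              pW1 = bpA$dW1 + bpB$dW1, pb1 = bpA$db1 + bpB$db1,
              pW2 = bpA$dW2 + bpB$dW2, pb2 = bpA$db2 + bpB$db2)
    if (loss == "simsiam" && !isTRUE(predictor$identity)) {
      g <- c(g, list(qW1 = lg$dpredictor$W1, qb1 = lg$dpredictor$b1,
                     qW2 = lg$dpredictor$W2, qb2 = lg$dpredictor$b2))
    }
    out$grads <- g
  }
  out
}

#' Train the two-stage encoder layerwise
#'
#' Fits a [two_stage_encoder()] by layerwise self-supervised learning: every
#' batch draws per-layer view pairs at that layer's patch/view scale (the
#' complexity schedule), computes each layer's feature-contrastive loss on
#' its own projected, pooled embeddings, and updates each stage's parameters
#' and projector only from its own loss. The layer-2 forward pass treats
#' stage 1 as frozen -- no gradient and no batch-norm statistic update
#' crosses the stage boundary. Optimization is Adam (lr = 0.001, no weight
#' decay by default); training stops when the summed validation loss stops
#' improving (see [early_stop()]). Deterministic given `config$seed`.
#'
#' @param corpus image array `size x size x n` (see [make_training_corpus()]).
#' @param schedule a `complexity_schedule` ([default_schedule()]).
#' @param encoder optional pre-initialized [two_stage_encoder()].
#' @param config a [train_config()].
#' @return Object of class `lcml`: list with `encoder`, `history`
#'   (data.frame of per-epoch train/validation losses per layer), `config`,
#'   `schedule`, `predictors`, `stopped_epoch`.
#' @export
lcml_train <- function(corpus, schedule = default_schedule(),
                       encoder = NULL, config = train_config()) {
  stopifnot(inherits(schedule, "complexity_schedule"),
            inherits(config, "train_config"))
  d <- dim(corpus)
  n <- d[3]
  max_patch <- max(vapply(schedule$layers, `[[`, integer(1), "patch_size"))
  if (d[1] < max_patch || d[2] < max_patch) {
    stopf("corpus images (%dx%d) are smaller than the largest patch size (%d)",
          d[1], d[2], max_patch)
  }
  n_layers <- length(schedule$layers)
  loss_by_layer <- rep(config$loss, length.out = n_layers)
  if (is.null(encoder)) {
    encoder <- two_stage_encoder(init_seed = derive_seed(config$seed, 1L))
  }
  out_dim <- encoder$projector_config$out_dim
  predictors <- lapply(seq_len(n_layers), function(l) {
    if (loss_by_layer[l] == "simsiam") {
      simsiam_predictor(out_dim, hidden = 64,
                        init_seed = derive_seed(config$seed, 50L + l))
    } else NULL
  })

  with_seed(config$seed, {
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    train_idx <- setdiff(seq_len(n), val_idx)

    adam_states <- lapply(seq_len(n_layers), function(l) {
      adam_init(layer_params(encoder, l, predictors[[l]]))
    })
    steps <- rep(0L, n_layers)
    history <- NULL
    stopped_epoch <- NA_integer_

    phases <- if (config$mode == "sequential") {
      as.list(seq_len(n_layers))
    } else list(seq_len(n_layers))

    for (phase in phases) {
      best_val <- Inf; wait <- 0L
      for (epoch in seq_len(config$max_epochs)) {
        ord <- sample(train_idx)
        batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
        tr_loss <- rep(0, n_layers); nb <- 0L
        for (bi in batches) {
          nb <- nb + 1L
          for (l in phase) {
            vb <- make_view_batch(corpus, bi, schedule$layers[[l]])
            lp <- layer_pass(encoder, l, vb, config, loss_by_layer[l],
                             predictors[[l]])
            encoder <- lp$enc
            tr_loss[l] <- tr_loss[l] + lp$loss
            steps[l] <- steps[l] + 1L
            upd <- adam_step(layer_params(encoder, l, predictors[[l]]),
                             lp$grads, adam_states[[l]], steps[l],
                             lr = config$learning_rate,
                             weight_decay = config$weight_decay)
            adam_states[[l]] <- upd$state
            pl <- put_layer_params(encoder, l, upd$params, predictors[[l]])
            encoder <- pl$enc
            if (!is.null(pl$predictor)) predictors[[l]] <- pl$predictor
          }
        }
        tr_loss <- tr_loss / nb
        # validation views are regenerated from a fixed seed so the
        # validation problem is identical across epochs
        val_loss <- rep(NA_real_, n_layers)
        for (l in seq_len(n_layers)) {
          vvb <- with_seed(derive_seed(config$seed, 900L + l),
                           make_view_batch(corpus, val_idx, schedule$layers[[l]]))
          vl <- layer_pass(encoder, l, vvb, config, loss_by_layer[l],
                           predictors[[l]], compute_grads = FALSE,
                           training = FALSE)
          val_loss[l] <- vl$loss
        }
        rec <- data.frame(phase = paste(phase, collapse = "+"), epoch = epoch)
        for (l in seq_len(n_layers)) {
          rec[[paste0("train_l", l)]] <- tr_loss[l]
          rec[[paste0("val_l", l)]] <- val_loss[l]
        }
        rec$train_total <- sum(tr_loss[phase])
        rec$val_total <- sum(val_loss[phase])
        history <- rbind(history, rec)

        v <- rec$val_total
        rel <- (best_val - v) / abs(best_val)
        if (is.finite(rel) && rel > config$stop_threshold) wait <- 0L else wait <- wait + 1L
        if (v < best_val) best_val <- v
        if (wait >= config$stop_patience) {
          stopped_epoch <- epoch
          break
        }
      }
    }

    structure(list(encoder = encoder, history = history, config = config,
                   schedule = schedule, predictors = predictors,
                   loss_by_layer = loss_by_layer,
                   stopped_epoch = stopped_epoch,
                   n_train = length(train_idx), n_val = n_val),
              class = "lcml")
  })
}

#' @rdname lcml_train
#' @export
train_layerwise <- lcml_train

#' @export
print.lcml <- function(x, ...) {
  h <- x$history
  cat("Layerwise complexity-matched encoder fit\n")
  cat(sprintf("  stages: %d (channels %d -> %d), losses: %s\n",
              length(x$schedule$layers),
              x$encoder$stage1$config$out_channels,
              x$encoder$stage2$config$out_channels,
              paste(x$loss_by_layer, collapse = ", ")))
  cat(sprintf("  epochs run: %d (%s mode), train images: %d, validation: %d\n",
              nrow(h), x$config$mode, x$n_train, x$n_val))
  last <- h[nrow(h), ]
  cat(sprintf("  final losses: layer 1 train %.4f / val %.4f; layer 2 train %.4f / val %.4f\n",
              last$train_l1, last$val_l1, last$train_l2, last$val_l2))
  invisible(x)
}

#' @export
summary.lcml <- function(object, ...) {
  h <- object$history
  s <- list(
    n_epochs = nrow(h),
    stopped_epoch = object$stopped_epoch,
    first = h[1, ], last = h[nrow(h), ],
    loss_reduction = c(layer1 = h$train_l1[1] - h$train_l1[nrow(h)],
                       layer2 = h$train_l2[1] - h$train_l2[nrow(h)]),
    receptive_fields = c(layer1 = receptive_field_extent(object$encoder, 1),
                         layer2 = receptive_field_extent(object$encoder, 2)),
    config = object$config)
  class(s) <- "summary.lcml"
  s
}

#' @export
print.summary.lcml <- function(x, ...) {
  cat(sprintf("Epochs: %d%s\n", x$n_epochs,
              if (is.na(x$stopped_epoch)) "" else sprintf(" (early stop at %d)", x$stopped_epoch)))
  cat(sprintf("Train loss layer 1: %.4f -> %.4f (reduction %.4f)\n",
              x$first$train_l1, x$last$train_l1, x$loss_reduction["layer1"]))
  cat(sprintf("Train loss layer 2: %.4f -> %.4f (reduction %.4f)\n",
              x$first$train_l2, x$last$train_l2, x$loss_reduction["layer2"]))
  cat(sprintf("Receptive fields: layer 1 = %d px, layer 2 = %d px\n",
              x$receptive_fields[1], x$receptive_fields[2]))
  invisible(x)
}

#' @export
plot.lcml <- function(x, ...) {
  h <- x$history
  ep <- seq_len(nrow(h))
  graphics::matplot(ep, cbind(h$train_l1, h$val_l1, h$train_l2, h$val_l2),
                    type = "l", lty = c(1, 2, 1, 2), col = c(2, 2, 4, 4),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("L1 train", "L1 val", "L2 train", "L2 val"),
                   lty = c(1, 2, 1, 2), col = c(2, 2, 4, 4), bty = "n")
  invisible(x)
}

#' @export
predict.lcml <- function(object, newdata, layer = 2,
                         include_projector = FALSE, ...) {
  extract_features(object$encoder, newdata, layer = layer,
                   include_projector = include_projector)
}

#' @export
coef.lcml <- function(object, ...) {
  e <- object$encoder
  list(stage1 = list(W = e$stage1$W, b = e$stage1$b, bn = e$stage1$bn),
       stage2 = list(W = e$stage2$W, b = e$stage2$b, bn = e$stage2$bn),
       proj1 = e$proj1, proj2 = e$proj2)
}

#' Complexity-ablation grid runner
#'
#' Trains one model per grid cell, varying the swept layer's patch size,
#' spatial deformation strength (see [deformation_strength_ladder()]) and
#' loss family while holding the other layer's parameters at the supplied
#' base schedule, then applies an evaluation hook to each trained model.
#' Each cell is seeded independently but reproducibly; completed cells are
#' cached as checkpoints in `cache_dir`, so rerunning a finished grid is
#' idempotent and interrupted grids resume. Cell failures are recorded and
#' the grid continues.
#'
#' @param corpus training image array.
#' @param patch_sizes integer vector of patch sizes for the swept layer
#'   (view size is scaled by the same 6/7 ratio as the defaults).
#' @param deformation_strengths character vector of ladder names
#'   (`"0"`,`"1"`,`"2"`,`"3"`,`"nonoverlap"`).
#' @param losses character vector of loss families.
#' @param eval_fn optional function(fit) -> numeric evaluation score.
#' @param layer which layer's parameters are swept (default 2).
#' @param base_schedule schedule providing the non-swept layer's parameters.
#' @param config a [train_config()]; each cell derives its own seed from
#'   `config$seed` and the cell definition.
#' @param cache_dir directory for cell checkpoints (created if needed).
#' @return data.frame with one row per cell: layer, patch_size, strength,
#'   loss, score, checkpoint path, error (NA if the cell succeeded).
#' @export
run_ablation_grid <- function(corpus, patch_sizes, deformation_strengths,
                              losses = "barlow", eval_fn = NULL, layer = 2,
                              base_schedule = default_schedule(),
                              config = train_config(),
                              cache_dir = file.path(tempdir(), "lcml_grid")) {
  if (!length(patch_sizes) || !length(deformation_strengths) || !length(losses)) {
    stopf("grids must be non-empty")
  }
  ladder <- deformation_strength_ladder()
  bad <- setdiff(deformation_strengths, names(ladder))
  if (length(bad)) stopf("unknown deformation strength(s): %s", paste(bad, collapse = ", "))
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(patch_size = patch_sizes, strength = deformation_strengths,
                      loss = losses, stringsAsFactors = FALSE)
  grid$layer <- layer
  grid$score <- NA_real_
  grid$checkpoint <- NA_character_
  grid$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    ck <- file.path(cache_dir, sprintf("cell_l%d_p%d_s%s_%s.rds",
                                       layer, cell$patch_size, cell$strength, cell$loss))
    grid$checkpoint[i] <- ck
    res <- tryCatch({
      if (file.exists(ck)) {
        fit <- readRDS(ck)
      } else {
        lad <- ladder[[cell$strength]]
        spec <- augment_spec(cell$patch_size,
                             max(8L, as.integer(round(cell$patch_size * 48 / 56))),
                             area_scale_range = lad$area_scale_range,
                             mode = lad$mode,
                             photometric = base_schedule$layers[[1]]$photometric)
        layers <- base_schedule$layers
        layers[[layer]] <- spec
        sch <- structure(list(layers = layers,
                              scale_factor = base_schedule$scale_factor),
                         class = "complexity_schedule")
        cfg <- config
        cfg$loss <- cell$loss
        cfg$seed <- derive_seed(config$seed, layer, cell$patch_size,
                                match(cell$strength, names(ladder)),
                                match(cell$loss, c("barlow", "simclr", "simsiam")))
        fit <- lcml_train(corpus, schedule = sch, config = cfg)
        saveRDS(fit, ck)
      }
      if (!is.null(eval_fn)) grid$score[i] <- eval_fn(fit)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) grid$error[i] <- res
  }
  grid[, c("layer", "patch_size", "strength", "loss", "score", "checkpoint", "error")]
}
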