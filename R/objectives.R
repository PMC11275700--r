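#' Cross-view feature cross-correlation matrix
#'
#' For embedding batches of two views (rows = batch samples, columns =
#' features), computes
#' `c_ij = sum_b zA[b,i] zB[b,j] / (||zA[,i]|| ||zB[,j]||)`.
#' Every entry lies in `[-1, 1]` (Cauchy-Schwarz). With `center = TRUE`,
#' per-feature batch means are subtracted first (the original redundancy-
#' reduction convention); the default implements the plain normalized
#' cross-moment.
#'
#' @param zA,zB numeric matrices `batch x features`, same shape, batch >= 2.
#' @param center logical; subtract per-feature batch means first.
#' @return `features x features` matrix.
#' @export
cross_correlation <- function(zA, zB, center = FALSE) {
  stopifnot(is.matrix(zA), is.matrix(zB), all(dim(zA) == dim(zB)))
  if (nrow(zA) < 2) stopf("batch size must be >= 2")
  if (center) {
    zA <- sweep(zA, 2, colMeans(zA))
    zB <- sweep(zB, 2, colMeans(zB))
  }
  na <- sqrt(colSums(zA^2)); nb <- sqrt(colSums(zB^2))
  bad <- which(na == 0 | nb == 0)
  if (length(bad)) {
    stopf("zero-norm feature column(s): %s", paste(bad, collapse = ", "))
  }
  crossprod(zA, zB) / outer(na, nb)
}

#' Barlow Twins redundancy-reduction loss
#'
#' `L = sum_i (1 - c_ii)^2 + lambda * sum_{i != j} c_ij^2`: the diagonal term
#' drives cross-view feature invariance, the off-diagonal term decorrelates
#' features. Non-negative, and zero iff `C` is the identity.
#'
#' @param C square cross-correlation matrix (see [cross_correlation()]).
#' @param lambda off-diagonal weight (>= 0), default 0.005.
#' @return Scalar loss.
#' @export
barlow_loss <- function(C, lambda = 0.005) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C), lambda >= 0)
  d <- diag(C)
  off <- C; diag(off) <- 0
  sum((1 - d)^2) + lambda * sum(off^2)
}

# loss + gradients w.r.t. the raw embeddings (used by the trainer)
barlow_grad <- function(zA, zB, lambda = 0.005, center = FALSE) {
  zA0 <- zA; zB0 <- zB
  if (center) {
    zA <- sweep(zA, 2, colMeans(zA))
    zB <- sweep(zB, 2, colMeans(zB))
  }
  na <- sqrt(colSums(zA^2)); nb <- sqrt(colSums(zB^2))
  if (any(na == 0) || any(nb == 0)) stopf("zero-norm feature column in embeddings")
  Ah <- sweep(zA, 2, na, "/")
  Bh <- sweep(zB, 2, nb, "/")
  C <- crossprod(Ah, Bh)
  d <- diag(C); off <- C; diag(off) <- 0
  loss <- sum((1 - d)^2) + lambda * sum(off^2)
  G <- 2 * lambda * off
  diag(G) <- -2 * (1 - d)
  sA <- rowSums(G * C)          # per-feature i
  sB <- colSums(G * C)          # per-feature j
  gA <- sweep(Bh %*% t(G) - sweep(Ah, 2, sA, "*"), 2, na, "/")
  gB <- sweep(Ah %*% G - sweep(Bh, 2, sB, "*"), 2, nb, "/")
  if (center) {
    gA <- sweep(gA, 2, colMeans(gA))
    gB <- sweep(gB, 2, colMeans(gB))
  }
  list(loss = loss, dzA = gA, dzB = gB, C = C)
}

#' Per-layer loss sum
#'
#' Computes each layer's feature-contrastive loss on its own view-pair
#' embeddings and their sum. The total is a monitoring/stopping quantity only:
#' gradient routing between layers is the trainer's contract, and each
#' layer's parameters receive gradients only from that layer's term.
#'
#' @param embeddings list with one element per layer, each a list with
#'   matrices `A` and `B` (`batch x features`).
#' @param lambda off-diagonal weight passed to [barlow_loss()].
#' @param center passed to [cross_correlation()].
#' @return List with `per_layer` (numeric vector) and `total`.
#' @export
layerwise_loss <- function(embeddings, lambda = 0.005, center = FALSE) {
  per <- vapply(embeddings, function(e) {
    barlow_loss(cross_correlation(e$A, e$B, center = center), lambda)
  }, numeric(1))
  list(per_layer = per, total = sum(per))
}

#' Sample-contrastive (normalized temperature cross-entropy) loss
#'
#' The SimCLR-style objective over the 2N-view batch: embeddings are
#' L2-normalized, each view is an anchor whose positive is the matching view
#' of the same image and whose negatives are all other views in the batch.
#'
#' @param zA,zB `batch x features` embedding matrices (batch >= 2).
#' @param temperature softmax temperature (> 0), default 0.1.
#' @return Scalar loss.
#' @export
sample_contrastive_loss <- function(zA, zB, temperature = 0.1) {
  sample_contrastive_grad(zA, zB, temperature)$loss
}

sample_contrastive_grad <- function(zA, zB, temperature = 0.1) {
  stopifnot(nrow(zA) >= 2, all(dim(zA) == dim(zB)), temperature > 0)
  n <- nrow(zA)
  z <- rbind(zA, zB)
  nz <- sqrt(rowSums(z^2))
  if (any(nz == 0)) stopf("zero-norm embedding row")
  zh <- z / nz
  s <- tcrossprod(zh) / temperature          # 2N x 2N
  pos <- c((n + 1):(2 * n), 1:n)             # index of each anchor's positive
  diag(s) <- -Inf                            # self-similarity excluded
  smax <- apply(s, 1, max)
  es <- exp(s - smax)
  denom <- rowSums(es)
  logp <- (s - smax) - log(denom)
  loss <- -mean(logp[cbind(seq_len(2 * n), pos)])
  P <- es / denom
  M <- P / (2 * n)
  M[cbind(seq_len(2 * n), pos)] <- M[cbind(seq_len(2 * n), pos)] - 1 / (2 * n)
  g <- (M + t(M)) %*% zh / temperature       # grad w.r.t. normalized rows
  # through row normalization
  gz <- (g - zh * rowSums(g * zh)) / nz
  list(loss = loss, dzA = gz[seq_len(n), , drop = FALSE],
       dzB = gz[(n + 1):(2 * n), , drop = FALSE])
}

#' SimSiam-style predictor
#'
#' Single-hidden-layer MLP used by the non-contrastive objective's asymmetric
#' branch. `hidden = 0` gives an identity predictor (no parameters).
#'
#' @param dim embedding dimensionality.
#' @param hidden hidden width (0 for identity).
#' @param init_seed integer seed.
#' @return Predictor parameter list of class `simsiam_predictor`.
#' @export
simsiam_predictor <- function(dim, hidden = 64, init_seed = 1L) {
  p <- if (hidden == 0) list(identity = TRUE) else with_seed(init_seed, {
    list(identity = FALSE,
         W1 = matrix(stats::rnorm(hidden * dim, 0, sqrt(2 / dim)), hidden, dim),
         b1 = rep(0, hidden),
         W2 = matrix(stats::rnorm(dim * hidden, 0, sqrt(2 / hidden)), dim, hidden),
         b2 = rep(0, dim))
  })
  structure(p, class = "simsiam_predictor")
}

predictor_forward <- function(pred, z) {
  if (isTRUE(pred$identity)) return(list(p = z))
  h <- z %*% t(pred$W1)
  h <- sweep(h, 2, pred$b1, "+")
  hm <- h > 0
  hr <- h * hm
  p <- sweep(hr %*% t(pred$W2), 2, pred$b2, "+")
  list(p = p, z = z, hm = hm, hr = hr)
}

# mean over rows of cosine similarity; returns d(mean cos)/dP (target blocked)
cosine_rows <- function(P, Tm) {
  np <- sqrt(rowSums(P^2)); nt <- sqrt(rowSums(Tm^2))
  if (any(np == 0) || any(nt == 0)) stopf("zero-norm embedding row")
  cs <- rowSums(P * Tm) / (np * nt)
  dP <- (Tm / (np * nt) - P * (cs / np^2)) / nrow(P)
  list(mean = mean(cs), dP = dP)
}

#' Non-contrastive (stop-gradient) loss
#'
#' Negative cosine similarity between the predictor output of one branch and
#' the gradient-blocked embedding of the other, symmetrized over branches
#' (the SimSiam recipe). The stop-gradient contract is structural: the
#' returned gradients with respect to the blocked branch of each term are
#' exactly zero.
#'
#' @param zA,zB `batch x features` embedding matrices.
#' @param predictor a [simsiam_predictor()].
#' @return Scalar loss in `[-1, 1]`.
#' @export
noncontrastive_loss <- function(zA, zB, predictor = simsiam_predictor(ncol(zA), 0)) {
  noncontrastive_grad(zA, zB, predictor)$loss
}

noncontrastive_grad <- function(zA, zB, predictor) {
  fA <- predictor_forward(predictor, zA)
  fB <- predictor_forward(predictor, zB)
  c1 <- cosine_rows(fA$p, zB)   # zB blocked here
  c2 <- cosine_rows(fB$p, zA)   # zA blocked here
  loss <- -(c1$mean + c2$mean) / 2
  dPA <- -c1$dP / 2
  dPB <- -c2$dP / 2
  back <- function(fw, dP) {
    if (isTRUE(predictor$identity)) {
      list(dz = dP, grads = NULL)
    } else {
      dhr <- dP %*% predictor$W2
      dh <- dhr * fw$hm
      list(dz = dh %*% predictor$W1,
           grads = list(W2 = t(dP) %*% fw$hr, b2 = colSums(dP),
                        W1 = t(dh) %*% fw$z, b1 = colSums(dh)))
    }
  }
  bA <- back(fA, dPA)
  bB <- back(fB, dPB)
  grads <- NULL
  if (!isTRUE(predictor$identity)) {
    grads <- Map(`+`, bA$grads, bB$grads)
  }
  # dzA gets gradient only through predictor branch A (branch B's target is
  # blocked); likewise dzB -- the stop-gradient contract.
  list(loss = loss, dzA = bA$dz, dzB = bB$dz, dpredictor = grads)
}
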