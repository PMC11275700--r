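# memoized geometry plans (conv/pool index maps), keyed by input shape
.plan_cache <- new.env(parent = emptyenv())

get_plan <- function(kind, ...) {
  key <- paste(kind, ..., sep = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  p <- if (kind == "conv") conv_plan(...) else pool_plan(...)
  .plan_cache[[key]] <- p
  p
}

#' Stage configuration
#'
#' Hyperparameters of one convolutional stage: convolution geometry, max
#' pooling geometry, and batch normalization. Each stage applies exactly two
#' nonlinearity types (ReLU rectification and max pooling). Defaults follow
#' the canonical first two stages of the AlexNet architecture.
#'
#' @param out_channels number of convolution filters.
#' @param kernel,stride,padding convolution geometry in pixels.
#' @param pool_kernel,pool_stride max-pooling geometry in pixels.
#' @param batch_norm logical; apply batch normalization after the convolution.
#' @return Object of class `stage_config`.
#' @export
stage_config <- function(out_channels, kernel, stride = 1, padding = 0,
                         pool_kernel = 3, pool_stride = 2, batch_norm = TRUE) {
  structure(list(out_channels = as.integer(out_channels), kernel = as.integer(kernel),
                 stride = as.integer(stride), padding = as.integer(padding),
                 pool_kernel = as.integer(pool_kernel),
                 pool_stride = as.integer(pool_stride), batch_norm = batch_norm),
            class = "stage_config")
}

#' @rdname stage_config
#' @param hidden_dim,out_dim projector MLP dimensions (single hidden layer).
#' @export
projector_config <- function(hidden_dim = 512, out_dim = 256) {
  structure(list(hidden_dim = as.integer(hidden_dim), out_dim = as.integer(out_dim)),
            class = "projector_config")
}

init_projector <- function(c_in, cfg) {
  list(W1 = matrix(stats::rnorm(cfg$hidden_dim * c_in, 0, sqrt(2 / c_in)),
                   cfg$hidden_dim, c_in),
       b1 = rep(0, cfg$hidden_dim),
       W2 = matrix(stats::rnorm(cfg$out_dim * cfg$hidden_dim, 0,
                                sqrt(2 / cfg$hidden_dim)),
                   cfg$out_dim, cfg$hidden_dim),
       b2 = rep(0, cfg$out_dim))
}

#' Two-stage convolutional encoder
#'
#' Builds an untrained two-stage encoder: stage 1 is conv(64 channels, 11x11,
#' stride 4, pad 2) -> batch norm -> ReLU -> maxpool(3, stride 2); stage 2
#' additionally applies conv(192 channels, 5x5, pad 2) -> batch norm -> ReLU
#' -> maxpool(3, stride 2). Capacity grows between stages through the channel
#' count (64 to 192) and receptive field. Each stage carries a projection
#' head: a single-hidden-layer MLP applied independently at every spatial
#' location of the feature map, followed by global average pooling.
#'
#' @param in_channels input image channels (1 = grayscale default).
#' @param stage1,stage2 [stage_config()]s; stage 2 must have more channels.
#' @param projector a [projector_config()] shared by both heads.
#' @param init_seed integer seed for He-normal weight initialization.
#' @return Object of class `two_stage_encoder`.
#' @export
two_stage_encoder <- function(in_channels = 1,
                              stage1 = stage_config(64, 11, 4, 2),
                              stage2 = stage_config(192, 5, 1, 2),
                              projector = projector_config(),
                              init_seed = 1L) {
  if (stage2$out_channels <= stage1$out_channels) {
    stopf("stage 2 must have more channels than stage 1 (capacity scaling)")
  }
  with_seed(init_seed, {
    k1 <- stage1$kernel^2 * in_channels
    k2 <- stage2$kernel^2 * stage1$out_channels
    enc <- list(
      in_channels = as.integer(in_channels),
      stage1 = list(config = stage1,
                    W = matrix(stats::rnorm(k1 * stage1$out_channels, 0, sqrt(2 / k1)),
                               k1, stage1$out_channels),
                    b = rep(0, stage1$out_channels),
                    bn = bn_init(stage1$out_channels)),
      stage2 = list(config = stage2,
                    W = matrix(stats::rnorm(k2 * stage2$out_channels, 0, sqrt(2 / k2)),
                               k2, stage2$out_channels),
                    b = rep(0, stage2$out_channels),
                    bn = bn_init(stage2$out_channels)),
      proj1 = init_projector(stage1$out_channels, projector),
      proj2 = init_projector(stage2$out_channels, projector),
      projector_config = projector
    )
  })
  structure(enc, class = "two_stage_encoder")
}

# Coerce images (matrix, h x w x B array, h x w x C x B array, or list of
# matrices) to an (h, w, C, B) batch array.
as_batch <- function(images, in_channels = 1) {
  if (is.list(images)) images <- simplify2array(images)
  d <- dim(images)
  if (is.null(d) || length(d) == 2) {
    images <- array(images, c(dim(as.matrix(images)), 1, 1))
  } else if (length(d) == 3) {
    images <- array(images, c(d[1], d[2], 1, d[3]))
    if (in_channels != 1) stopf("expected %d-channel input", in_channels)
  } else if (length(d) != 4) stopf("cannot interpret image batch of rank %d", length(d))
  images
}

# Full forward through one stage with caches for backprop. Returns the
# (possibly BN-updated) stage as well.
stage_forward_one <- function(stage, x, training) {
  cfg <- stage$config
  d <- dim(x)
  cp <- get_plan("conv", d[1], d[2], d[3], cfg$kernel, cfg$kernel,
                 cfg$stride, cfg$padding)
  cv <- conv_forward(x, stage$W, stage$b, cp)
  h <- cv$y
  bn_cache <- NULL
  if (cfg$batch_norm) {
    bf <- bn_forward(h, stage$bn, training)
    h <- bf$y; stage$bn <- bf$bn; bn_cache <- bf$cache
  }
  rl <- relu_forward(h)
  pp <- get_plan("pool", dim(rl$y)[1], dim(rl$y)[2], cfg$pool_kernel, cfg$pool_stride)
  mp <- maxpool_forward(rl$y, pp)
  list(y = mp$y, stage = stage,
       cache = list(conv = cv, conv_plan = cp, bn = bn_cache,
                    relu_mask = rl$mask, pool = mp, pool_plan = pp))
}

# Backward through one stage; returns parameter gradients (and optionally dx).
stage_backward_one <- function(stage, dy, cache, need_dx = FALSE) {
  cfg <- stage$config
  dh <- maxpool_backward(dy, cache$pool, cache$pool_plan)
  dh <- relu_backward(dh, cache$relu_mask)
  dgamma <- dbeta <- NULL
  if (cfg$batch_norm) {
    bb <- bn_backward(dh, stage$bn, cache$bn)
    dh <- bb$dx; dgamma <- bb$dgamma; dbeta <- bb$dbeta
  }
  cb <- conv_backward(dh, stage$W, cache$conv, cache$conv_plan)
  list(dW = cb$dw, db = cb$db, dgamma = dgamma, dbeta = dbeta,
       dx = if (need_dx) cb$dx else NULL)
}

#' Forward pass through encoder stages
#'
#' Runs images through stage 1 (`layer = 1`) or stages 1 then 2 (`layer = 2`)
#' in inference mode (batch norm uses running statistics), returning the
#' post-pooling feature map.
#'
#' @param encoder a [two_stage_encoder()].
#' @param layer 1 or 2.
#' @param images image batch: matrix, `h x w x B` array, `h x w x C x B`
#'   array, or list of matrices.
#' @return Feature map array `(h', w', channels, batch)`.
#' @export
stage_forward <- function(encoder, layer, images) {
  stopifnot(inherits(encoder, "two_stage_encoder"), layer %in% c(1, 2))
  x <- as_batch(images, encoder$in_channels)
  s1 <- stage_forward_one(encoder$stage1, x, training = FALSE)
  if (layer == 1) return(s1$y)
  stage_forward_one(encoder$stage2, s1$y, training = FALSE)$y
}

# projector forward with cache: feature map (h,w,C,B) -> batch x out_dim
project_and_pool_full <- function(fm, proj) {
  d <- dim(fm)
  l_dim <- d[1] * d[2]; b <- d[4]
  a <- aperm(fm, c(3, 1, 2, 4))
  dim(a) <- c(d[3], l_dim * b)
  h <- proj$W1 %*% a + proj$b1
  hm <- h > 0
  hr <- h * hm
  z <- proj$W2 %*% hr + proj$b2                   # out x (L*B)
  out_dim <- nrow(proj$W2)
  zp <- matrix(0, out_dim, b)
  zarr <- z; dim(zarr) <- c(out_dim, l_dim, b)
  for (l in seq_len(l_dim)) zp <- zp + matrix(zarr[, l, ], out_dim, b)
  zp <- zp / l_dim
  list(z = t(zp), cache = list(a = a, hm = hm, hr = hr, d = d, l_dim = l_dim, b = b))
}

project_and_pool_backward <- function(dz, proj, cache, need_dx = TRUE) {
  l_dim <- cache$l_dim; b <- cache$b; d <- cache$d
  dzp <- t(dz) / l_dim                            # out x B
  dzm <- dzp[, rep(seq_len(b), each = l_dim), drop = FALSE]  # out x (L*B)
  dW2 <- dzm %*% t(cache$hr)
  db2 <- rowSums(dzm)
  dhr <- crossprod(proj$W2, dzm)
  dh <- dhr * cache$hm
  dW1 <- dh %*% t(cache$a)
  db1 <- rowSums(dh)
  dx <- NULL
  if (need_dx) {
    da <- crossprod(proj$W1, dh)                  # C x (L*B)
    dim(da) <- c(d[3], d[1], d[2], d[4])
    dx <- aperm(da, c(2, 3, 1, 4))
  }
  list(dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2, dx = dx)
}

#' Per-location projection followed by global average pooling
#'
#' Applies the projector MLP independently at every spatial location of the
#' feature map and averages the projected vectors over space, yielding one
#' embedding per image.
#'
#' @param feature_map array `(h, w, channels, batch)`.
#' @param projector projector parameter list (`W1`, `b1`, `W2`, `b2`), e.g.
#'   `encoder$proj1`.
#' @return Matrix `batch x out_dim`.
#' @export
project_and_pool <- function(feature_map, projector) {
  d <- dim(feature_map)
  if (length(d) != 4) stopf("feature_map must be (h, w, channels, batch)")
  if (ncol(projector$W1) != d[3]) {
    stopf("projector input dim %d does not match channel count %d",
          ncol(projector$W1), d[3])
  }
  project_and_pool_full(feature_map, projector)$z
}

#' Extract per-image feature vectors
#'
#' Deterministic inference-mode features for downstream neural-predictivity
#' regression: by default the flattened post-stage activations; with
#' `include_projector = TRUE` the pooled projector embeddings.
#'
#' @param encoder a [two_stage_encoder()].
#' @param images image batch (see [stage_forward()]).
#' @param layer 1 or 2.
#' @param include_projector logical.
#' @param batch_size images per forward chunk (memory control).
#' @return Matrix `images x features`.
#' @export
extract_features <- function(encoder, images, layer = 2,
                             include_projector = FALSE, batch_size = 64) {
  x <- as_batch(images, encoder$in_channels)
  n <- dim(x)[4]
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  out <- NULL
  for (ch in chunks) {
    fm <- stage_forward(encoder, layer, x[, , , ch, drop = FALSE])
    feats <- if (include_projector) {
      project_and_pool(fm, if (layer == 1) encoder$proj1 else encoder$proj2)
    } else {
      t(matrix(fm, prod(dim(fm)[1:3]), dim(fm)[4]))
    }
    out <- rbind(out, feats)
  }
  out
}

#' Analytic receptive field extent
#'
#' Receptive field (in input pixels) of one unit of the post-pooling output of
#' the given layer, composed from kernel/stride geometry.
#'
#' @param encoder a [two_stage_encoder()].
#' @param layer 1 or 2.
#' @return Receptive field side length in pixels.
#' @export
receptive_field_extent <- function(encoder, layer = 2) {
  rf <- 1; jump <- 1
  stages <- list(encoder$stage1$config, encoder$stage2$config)[seq_len(layer)]
  for (cfg in stages) {
    rf <- rf + (cfg$kernel - 1) * jump
    jump <- jump * cfg$stride
    rf <- rf + (cfg$pool_kernel - 1) * jump
    jump <- jump * cfg$pool_stride
  }
  rf
}

#' Save / load encoder checkpoints
#'
#' Single-file archive of all stage and projector parameters, configs and
#' batch-norm running statistics; round-trips bit-exactly.
#'
#' @param encoder a [two_stage_encoder()] (or a full `lcml` fit).
#' @param path file path.
#' @export
save_checkpoint <- function(encoder, path) {
  saveRDS(encoder, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
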