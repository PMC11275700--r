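# Fourier-domain steerable pyramid: polar-separable raised-cosine radial
# filters with cos^(K-1) angular tuning, built as a tight frame (squared
# filter magnitudes sum to one over the plane), with quadrature-pair
# (analytic) oriented subbands obtained by half-plane masking. Dyadic
# downsampling is exact spectrum cropping, lossless because the recursive
# lowpass vanishes at and beyond half-band.

#' Steerable pyramid configuration
#'
#' @param n_orientations number of orientation bands (>= 2), default 4.
#' @param n_scales number of dyadic scales (>= 1), default 3.
#' @param pool_window,pool_stride spatial energy-pooling geometry in subband
#'   pixels (window >= stride).
#' @return Object of class `pyramid_config`.
#' @export
pyramid_config <- function(n_orientations = 4, n_scales = 3,
                           pool_window = 4, pool_stride = 2) {
  if (n_orientations < 2) stopf("n_orientations must be >= 2")
  if (n_scales < 1) stopf("n_scales must be >= 1")
  if (pool_window < pool_stride) stopf("pool_window must be >= pool_stride")
  structure(list(n_orientations = as.integer(n_orientations),
                 n_scales = as.integer(n_scales),
                 pool_window = as.integer(pool_window),
                 pool_stride = as.integer(pool_stride)),
            class = "pyramid_config")
}

# raised-cosine lowpass with transition [cut/2 scaled]: value 1 for r <= lo,
# cos((pi/2) * log2(r/lo)) for lo < r < 2*lo, 0 beyond
rcos_low <- function(r, lo) {
  out <- numeric(length(r))
  out[r <= lo] <- 1
  tr <- r > lo & r < 2 * lo
  out[tr] <- cos((pi / 2) * log2(r[tr] / lo))
  out
}

polar_grid <- function(n) {
  w <- fft_freqs(n)
  WX <- matrix(w, n, n, byrow = TRUE)
  WY <- matrix(w, n, n)
  list(r = sqrt(WX^2 + WY^2), th = atan2(WY, WX))
}

angular_filters <- function(th, k_orient) {
  aK <- 1 / sqrt(k_orient * choose(2 * k_orient - 2, k_orient - 1) /
                   4^(k_orient - 1))
  lapply(seq_len(k_orient), function(k) {
    th0 <- (k - 1) * pi / k_orient
    cs <- cos(th - th0)
    g <- aK * abs(cs)^(k_orient - 1)
    mask <- ifelse(cs > 1e-12, 1, ifelse(cs < -1e-12, 0, 0.5))
    list(g = g, mask = mask)
  })
}

crop_spectrum <- function(X) {
  n <- nrow(X); m <- n / 2
  keep <- c(seq_len(m / 2), (n - m / 2 + 1):n)
  X[keep, keep] / 4
}

pad_spectrum <- function(X) {
  m <- nrow(X); n <- 2 * m
  out <- matrix(0 + 0i, n, n)
  keep <- c(seq_len(m / 2), (n - m / 2 + 1):n)
  out[keep, keep] <- X * 4
  out
}

#' Steerable pyramid decomposition
#'
#' Decomposes an image into complex (quadrature-pair) oriented subbands at
#' dyadically downsampled scales, plus real high- and low-pass residuals.
#' The filters form a tight frame: [steerable_reconstruct()] recovers the
#' input to within numerical tolerance.
#'
#' @param image square numeric matrix; side must be divisible by
#'   `2^n_scales` and leave at least 8 px at the coarsest scale.
#' @param config a [pyramid_config()].
#' @return Object of class `subband_stack`: list with `bands` (list indexed
#'   `[[scale]][[orientation]]` of complex matrices), `highpass`, `lowpass`,
#'   `config`, `size`.
#' @export
steerable_decompose <- function(image, config = pyramid_config()) {
  stopifnot(inherits(config, "pyramid_config"))
  n <- nrow(image)
  if (n != ncol(image)) stopf("image must be square")
  if (n %% (2^config$n_scales) != 0) {
    stopf("image side %d must be divisible by 2^%d", n, config$n_scales)
  }
  if (n / 2^config$n_scales < 8) {
    stopf("image side %d too small for %d scales", n, config$n_scales)
  }
  g0 <- polar_grid(n)
  L0 <- rcos_low(g0$r, pi / 2)
  H0 <- sqrt(pmax(0, 1 - L0^2))
  X <- stats::fft(image)
  highpass <- Re(stats::fft(X * H0, inverse = TRUE)) / n^2
  X <- X * L0
  bands <- vector("list", config$n_scales)
  for (s in seq_len(config$n_scales)) {
    ns <- nrow(X)
    g <- polar_grid(ns)
    L <- rcos_low(g$r, pi / 4)
    H <- sqrt(pmax(0, 1 - L^2))
    af <- angular_filters(g$th, config$n_orientations)
    bands[[s]] <- lapply(af, function(a) {
      stats::fft(X * H * a$g * 2 * a$mask, inverse = TRUE) / ns^2
    })
    X <- crop_spectrum(X * L)
  }
  nl <- nrow(X)
  lowpass <- Re(stats::fft(X, inverse = TRUE)) / nl^2
  structure(list(bands = bands, highpass = highpass, lowpass = lowpass,
                 config = config, size = n),
            class = "subband_stack")
}

#' @rdname steerable_decompose
#' @param stack a `subband_stack`.
#' @export
steerable_reconstruct <- function(stack) {
  config <- stack$config
  X <- stats::fft(stack$lowpass)
  for (s in rev(seq_len(config$n_scales))) {
    X <- pad_spectrum(X)
    ns <- nrow(X)
    g <- polar_grid(ns)
    L <- rcos_low(g$r, pi / 4)
    H <- sqrt(pmax(0, 1 - L^2))
    af <- angular_filters(g$th, config$n_orientations)
    X <- X * L
    for (k in seq_len(config$n_orientations)) {
      X <- X + stats::fft(Re(stack$bands[[s]][[k]])) * H * af[[k]]$g
    }
  }
  n <- stack$size
  g0 <- polar_grid(n)
  L0 <- rcos_low(g0$r, pi / 2)
  H0 <- sqrt(pmax(0, 1 - L0^2))
  X <- X * L0 + stats::fft(stack$highpass) * H0
  Re(stats::fft(X, inverse = TRUE)) / n^2
}

#' Simple-cell responses
#'
#' Halfwave-rectified versions of the real and imaginary parts of each
#' oriented subband: four polarity/phase channels per subband, all
#' non-negative.
#'
#' @param stack a `subband_stack` from [steerable_decompose()].
#' @return Nested list `[[scale]][[orientation]]` of lists with elements
#'   `even_on`, `even_off`, `odd_on`, `odd_off`.
#' @export
simple_cells <- function(stack) {
  stopifnot(inherits(stack, "subband_stack"))
  lapply(stack$bands, function(sc) lapply(sc, function(b) {
    re <- Re(b); im <- Im(b)
    list(even_on = pmax(re, 0), even_off = pmax(-re, 0),
         odd_on = pmax(im, 0), odd_off = pmax(-im, 0))
  }))
}

#' Complex-cell responses
#'
#' Quadrature energy: the modulus of each complex subband, which is locally
#' invariant to the spatial phase of band-limited input.
#'
#' @param stack a `subband_stack`.
#' @return Nested list `[[scale]][[orientation]]` of non-negative matrices.
#' @export
complex_cells <- function(stack) {
  stopifnot(inherits(stack, "subband_stack"))
  lapply(stack$bands, function(sc) lapply(sc, Mod))
}

#' Spatial L2 (energy) pooling
#'
#' Square root of the windowed mean of squared responses (root-mean, so a
#' constant map is a fixed point), over valid windows only.
#'
#' @param map numeric matrix of non-negative responses.
#' @param pool_window,pool_stride window and stride in pixels.
#' @return Pooled matrix.
#' @export
l2_pool <- function(map, pool_window = 4, pool_stride = 2) {
  h <- nrow(map); w <- ncol(map)
  if (pool_window > h || pool_window > w) {
    stopf("pool window %d exceeds map extent %dx%d", pool_window, h, w)
  }
  # summed-area table of squares
  sat <- apply(apply(map^2, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  oy <- seq(1, h - pool_window + 1, by = pool_stride)
  ox <- seq(1, w - pool_window + 1, by = pool_stride)
  out <- matrix(0, length(oy), length(ox))
  k <- pool_window
  for (i in seq_along(oy)) {
    y0 <- oy[i]
    out[i, ] <- sat[y0 + k, ox + k] - sat[y0, ox + k] -
      sat[y0 + k, ox] + sat[y0, ox]
  }
  sqrt(pmax(out, 0) / k^2)
}

#' V1 feature vector
#'
#' The hand-crafted V1 baseline representation: energy-pooled simple- and
#' complex-cell maps across all scales and orientations, concatenated into
#' one non-negative feature vector per image.
#'
#' @param image square numeric matrix.
#' @param config a [pyramid_config()].
#' @return Numeric vector (length fixed by `config` and image size).
#' @export
v1_features <- function(image, config = pyramid_config()) {
  stack <- steerable_decompose(image, config)
  sc <- simple_cells(stack)
  cc <- complex_cells(stack)
  feats <- list()
  for (s in seq_along(stack$bands)) {
    for (k in seq_along(stack$bands[[s]])) {
      for (ch in sc[[s]][[k]]) {
        feats[[length(feats) + 1]] <- as.vector(
          l2_pool(ch, stack$config$pool_window, stack$config$pool_stride))
      }
      feats[[length(feats) + 1]] <- as.vector(
        l2_pool(cc[[s]][[k]], stack$config$pool_window, stack$config$pool_stride))
    }
  }
  unlist(feats, use.names = FALSE)
}

#' V1 feature matrix for a stimulus set
#'
#' Applies [v1_features()] to every image of a stimulus set.
#'
#' @param stimuli a `stimulus_set`.
#' @param config a [pyramid_config()].
#' @return Matrix `images x features`.
#' @export
v1_feature_matrix <- function(stimuli, config = pyramid_config()) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  n <- dim(stimuli$images)[3]
  f1 <- v1_features(stimuli$images[, , 1], config)
  out <- matrix(0, n, length(f1))
  out[1, ] <- f1
  for (i in seq_len(n)[-1]) out[i, ] <- v1_features(stimuli$images[, , i], config)
  out
}
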