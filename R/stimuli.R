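#' Texture family specification
#'
#' Parameterizes one synthetic texture family. Families are built from
#' oriented band-pass filtered noise with a controlled amount of cross-scale
#' phase alignment, which endows samples with higher-order (non-Gaussian,
#' phase-dependent) structure that phase scrambling destroys -- the property
#' the texture-vs-noise evaluation statistics rely on.
#'
#' @param orientation numeric, dominant orientation in radians.
#' @param orientation_bw angular bandwidth (radians, sd of the Gaussian
#'   orientation tuning of the generating filter).
#' @param freq dominant spatial frequency in cycles per image.
#' @param freq_bw radial bandwidth in octaves.
#' @param cross_scale cross-scale correlation strength in `[0, 1]`: the mixing
#'   weight of the phase-aligned double-frequency band relative to an
#'   independent band. 0 gives (near) Gaussian texture, 1 maximally aligned
#'   edge-like structure.
#' @param contrast_exponent pointwise amplitude exponent (> 0); values < 1
#'   compress, > 1 sparsify the contrast distribution.
#' @param rms_contrast target root-mean-square contrast of the final image.
#' @param seed integer seed identifying the family.
#' @return An object of class `texture_family_spec`.
#' @export
texture_family_spec <- function(orientation = 0, orientation_bw = 0.4,
                                freq = 8, freq_bw = 0.8,
                                cross_scale = 0.8, contrast_exponent = 1.5,
                                rms_contrast = 0.18, seed = 1L) {
  if (orientation_bw <= 0) stopf("orientation_bw must be positive")
  if (freq <= 0) stopf("freq must be positive")
  if (cross_scale < 0 || cross_scale > 1) stopf("cross_scale must lie in [0, 1]")
  if (contrast_exponent <= 0) stopf("contrast_exponent must be positive")
  structure(list(orientation = orientation, orientation_bw = orientation_bw,
                 freq = freq, freq_bw = freq_bw, cross_scale = cross_scale,
                 contrast_exponent = contrast_exponent,
                 rms_contrast = rms_contrast, seed = as.integer(seed)),
            class = "texture_family_spec")
}

# Frequency-grid helper: centred angular frequencies (radians/sample) for an
# n-point DFT, in unshifted (fft) order.
fft_freqs <- function(n) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2 - 1), -(n / 2):-1)
  2 * pi * k / n
}

# Oriented log-Gaussian band filter on the fft grid (even-symmetric, real).
oriented_band_filter <- function(size, freq_cpi, freq_bw_oct, theta0, theta_bw) {
  wx <- fft_freqs(size); wy <- fft_freqs(size)
  WX <- matrix(wx, size, size, byrow = TRUE)
  WY <- matrix(wy, size, size)
  r <- sqrt(WX^2 + WY^2)
  th <- atan2(WY, WX)
  w0 <- 2 * pi * freq_cpi / size
  rad <- exp(-(log2(pmax(r, 1e-12) / w0))^2 / (2 * freq_bw_oct^2))
  rad[r == 0] <- 0
  # orientation tuning symmetric under theta -> theta + pi
  dth <- th - theta0
  dth <- atan2(sin(2 * dth), cos(2 * dth)) / 2  # wrapped to [-pi/2, pi/2]
  ang <- exp(-dth^2 / (2 * theta_bw^2))
  rad * ang
}

band_noise <- function(size, filt) {
  w <- matrix(stats::rnorm(size * size), size, size)
  Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / (size * size)
}

#' Generate samples of one synthetic texture family
#'
#' Draws `n_samples` independent realizations sharing the family's orientation
#' and frequency statistics. Each sample combines a base oriented band with a
#' double-frequency band whose phases are partially aligned to the base
#' (strength `spec$cross_scale`), followed by a pointwise contrast
#' nonlinearity. This creates family-graded higher-order structure while
#' keeping generation deterministic under a fixed seed.
#'
#' @param spec a [texture_family_spec()].
#' @param n_samples number of images (>= 1).
#' @param size image edge length in pixels (>= 32).
#' @param rng_seed integer seed; combined with `spec$seed` and the sample index
#'   so each sample is reproducible independently.
#' @return List of `n_samples` matrices (`size` x `size`) with values in `[0, 1]`.
#' @export
make_texture_family <- function(spec, n_samples, size = 64, rng_seed = 1L) {
  stopifnot(inherits(spec, "texture_family_spec"))
  if (n_samples < 1) stopf("n_samples must be >= 1")
  if (size < 32) stopf("size must be >= 32")
  if (2 * spec$freq > size / 2) {
    stopf("size %d cannot support the family's double-frequency band (%g cycles/image > Nyquist)",
          size, 2 * spec$freq)
  }
  f1 <- oriented_band_filter(size, spec$freq, spec$freq_bw,
                             spec$orientation, spec$orientation_bw)
  f2 <- oriented_band_filter(size, 2 * spec$freq, spec$freq_bw,
                             spec$orientation, spec$orientation_bw)
  lapply(seq_len(n_samples), function(s) {
    with_seed(derive_seed(rng_seed, spec$seed, s), {
      base <- band_noise(size, f1)
      base <- base / stats::sd(base)
      # phase-aligned double-frequency energy from the squared base band
      aligned <- Re(stats::fft(stats::fft(base^2) * f2, inverse = TRUE)) / (size * size)
      if (stats::sd(aligned) > 0) aligned <- aligned / stats::sd(aligned)
      indep <- band_noise(size, f2)
      indep <- indep / stats::sd(indep)
      x <- base + 0.7 * (spec$cross_scale * aligned + (1 - spec$cross_scale) * indep)
      x <- sign(x) * abs(x / stats::sd(x))^spec$contrast_exponent
      x <- x - mean(x)
      x <- x / max(stats::sd(x), 1e-12) * spec$rms_contrast + 0.5
      clip01(x)
    })
  })
}

#' Spectrally-matched noise by phase scrambling
#'
#' Returns an image with the same Fourier amplitude spectrum as the input but
#' uniformly random phases (Hermitian symmetry preserved, so the output is
#' real). The DC component is kept exactly, so the output mean equals the
#' input mean. Values falling outside `[0, 1]` are clipped; the clipped
#' fraction is recorded in attribute `"clip_fraction"` and generation is
#' rejected if it exceeds 5%.
#'
#' @param image single-channel numeric matrix (an H x W x 3 array is scrambled
#'   per channel with shared phases).
#' @param rng_seed integer seed.
#' @return Matrix (or array) of the same dimensions, values in `[0, 1]`, with
#'   attributes `clip_fraction` and `unclipped` (the exact spectrally-matched
#'   image before clipping, on which amplitude preservation is exact).
#' @export
spectral_match_noise <- function(image, rng_seed = 1L) {
  if (!all(is.finite(image))) stopf("image contains non-finite pixels")
  scramble <- function(mat, phase_fft) {
    X <- stats::fft(mat)
    mag_w <- Mod(phase_fft)
    unit <- phase_fft / ifelse(mag_w == 0, 1, mag_w)
    Y <- Mod(X) * unit
    Y[1, 1] <- X[1, 1]  # preserve mean (and its sign)
    Re(stats::fft(Y, inverse = TRUE)) / length(mat)
  }
  if (length(dim(image)) == 3) {
    ph <- with_seed(rng_seed,
                    stats::fft(matrix(stats::rnorm(prod(dim(image)[1:2])),
                                      dim(image)[1], dim(image)[2])))
    out <- image
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- scramble(image[, , ch], ph)
  } else {
    ph <- with_seed(rng_seed,
                    stats::fft(matrix(stats::rnorm(length(image)),
                                      nrow(image), ncol(image))))
    out <- scramble(image, ph)
  }
  clip_frac <- mean(out < 0 | out > 1)
  if (clip_frac > 0.05) {
    stopf("phase scrambling clipped %.1f%% of pixels (> 5%%)", 100 * clip_frac)
  }
  unclipped <- out
  out <- clip01(out)
  attr(out, "clip_fraction") <- clip_frac
  attr(out, "unclipped") <- unclipped
  out
}

default_family_specs <- function(n_families, rng_seed) {
  # graded, deterministic family parameters: orientations tile [0, pi),
  # frequency alternates across a band, cross-scale strength ramps so the
  # families span weak-to-strong higher-order structure
  lapply(seq_len(n_families), function(f) {
    texture_family_spec(
      orientation = (f - 1) * pi / n_families,
      orientation_bw = 0.25 + 0.5 * ((f - 1) %% 4) / 3,
      freq = c(6, 8, 10)[1 + (f - 1) %% 3],
      freq_bw = 0.8,
      cross_scale = 0.15 + 0.8 * (f - 1) / max(n_families - 1, 1),
      contrast_exponent = 1.2 + 0.6 * ((f - 1) %% 2),
      seed = derive_seed(rng_seed, 7777L, f)
    )
  })
}

#' Build a texture / spectrally-matched-noise stimulus set
#'
#' Generates `n_families` synthetic texture families with `n_samples` images
#' each, plus one spectrally-matched noise counterpart per texture image
#' (identical family and sample ids), mirroring the design of the classic
#' V2 texture-modulation stimulus sets: with the defaults, 15 families x 15
#' samples x two conditions = 450 images.
#'
#' @param n_families,n_samples design counts (>= 1 each).
#' @param size image edge length in pixels.
#' @param rng_seed integer seed.
#' @param specs optional list of `n_families` [texture_family_spec()] objects;
#'   by default a graded family set derived from `rng_seed`.
#' @return A `stimulus_set`: list with `images` (array `size x size x n`),
#'   `meta` (data.frame: `family_id`, `sample_id`, `condition`), `size`.
#' @export
build_v2_stimulus_set <- function(n_families = 15, n_samples = 15, size = 64,
                                  rng_seed = 1L, specs = NULL) {
  if (n_families < 1 || n_samples < 1) stopf("n_families and n_samples must be >= 1")
  if (is.null(specs)) specs <- default_family_specs(n_families, rng_seed)
  stopifnot(length(specs) == n_families)
  n_total <- n_families * n_samples * 2
  images <- array(0, c(size, size, n_total))
  meta <- data.frame(family_id = integer(n_total), sample_id = integer(n_total),
                     condition = character(n_total), stringsAsFactors = FALSE)
  k <- 0
  for (f in seq_len(n_families)) {
    tex <- make_texture_family(specs[[f]], n_samples, size,
                               rng_seed = derive_seed(rng_seed, 11L, f))
    for (s in seq_len(n_samples)) {
      k <- k + 1
      images[, , k] <- tex[[s]]
      meta[k, ] <- list(f, s, "texture")
      k <- k + 1
      nz <- spectral_match_noise(tex[[s]],
                                 rng_seed = derive_seed(rng_seed, 13L, f, s))
      images[, , k] <- nz
      meta[k, ] <- list(f, s, "noise")
    }
  }
  structure(list(images = images, meta = meta, size = size),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("stimulus_set: %d images (%d x %d), %d families x %d samples x {texture, noise}\n",
              dim(x$images)[3], x$size, x$size,
              length(unique(x$meta$family_id)),
              length(unique(x$meta$sample_id))))
  invisible(x)
}

#' Generate a synthetic training corpus
#'
#' Produces natural-image-like composites: 1/f-amplitude-spectrum noise
#' backgrounds with superimposed oriented band-limited structure, sized for
#' the augmentation pipeline. A stand-in training distribution with the
#' coarse spectral statistics of natural images (radially averaged power
#' spectrum slope near -2 on log-log axes).
#'
#' @param n_images number of images (>= 1).
#' @param size image edge length (must be at least the largest configured
#'   central-patch size; default 224).
#' @param rng_seed integer seed.
#' @return Array `size x size x n_images` with values in `[0, 1]`.
#' @export
make_training_corpus <- function(n_images, size = 224, rng_seed = 1L) {
  if (n_images < 1) stopf("n_images must be >= 1")
  if (size < 32) stopf("size must be >= 32")
  wx <- fft_freqs(size)
  WX <- matrix(wx, size, size, byrow = TRUE)
  WY <- matrix(wx, size, size)
  r <- sqrt(WX^2 + WY^2)
  amp <- 1 / pmax(r, 2 * pi / size)  # 1/f amplitude -> 1/f^2 power
  amp[1, 1] <- 0
  out <- array(0, c(size, size, n_images))
  for (i in seq_len(n_images)) {
    out[, , i] <- with_seed(derive_seed(rng_seed, 101L, i), {
      w <- matrix(stats::rnorm(size * size), size, size)
      bg <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (size * size)
      bg <- bg / stats::sd(bg)
      # superimpose a few oriented band-limited elements
      n_el <- sample(2:4, 1)
      for (el in seq_len(n_el)) {
        f <- oriented_band_filter(size, stats::runif(1, 6, 24), 0.7,
                                  stats::runif(1, 0, pi), stats::runif(1, 0.2, 0.5))
        e <- band_noise(size, f)
        # localize with a Gaussian window at a random position
        cx <- stats::runif(1, 0.2, 0.8) * size
        cy <- stats::runif(1, 0.2, 0.8) * size
        sg <- stats::runif(1, 0.08, 0.2) * size
        gx <- exp(-((seq_len(size) - cx)^2) / (2 * sg^2))
        gy <- exp(-((seq_len(size) - cy)^2) / (2 * sg^2))
        win <- outer(gy, gx)
        bg <- bg + 0.8 * e / stats::sd(e) * win
      }
      x <- bg - mean(bg)
      clip01(x / stats::sd(x) * 0.16 + 0.5)
    })
  }
  out
}

#' Write / read a stimulus set on disk
#'
#' Writes one lossless 16-bit grayscale TIFF per image plus a CSV metadata
#' table (`filename`, `family_id`, `sample_id`, `condition`).
#'
#' @param x a `stimulus_set`.
#' @param dir output directory (created if needed).
#' @return `write_stimulus_set`: invisibly, the metadata data.frame;
#'   `read_stimulus_set`: the reconstructed `stimulus_set` (16-bit quantized).
#' @export
write_stimulus_set <- function(x, dir) {
  stopifnot(inherits(x, "stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(x$images)[3]
  fn <- sprintf("img_%04d_%s_f%02d_s%02d.tiff", seq_len(n),
                substr(x$meta$condition, 1, 3), x$meta$family_id, x$meta$sample_id)
  for (i in seq_len(n)) {
    tiff::writeTIFF(x$images[, , i], file.path(dir, fn[i]), bits.per.sample = 16L)
  }
  meta <- cbind(filename = fn, x$meta)
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(meta)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  first <- tiff::readTIFF(file.path(dir, meta$filename[1]))
  size <- nrow(first)
  images <- array(0, c(size, size, nrow(meta)))
  for (i in seq_len(nrow(meta))) {
    images[, , i] <- tiff::readTIFF(file.path(dir, meta$filename[i]))
  }
  structure(list(images = images,
                 meta = meta[, c("family_id", "sample_id", "condition")],
                 size = size),
            class = "stimulus_set")
}
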