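#' Augmentation specification for one layer
#'
#' Bundles the parameters that set the complexity of one layer's learning
#' problem: the central patch size (feature complexity), the output view size,
#' the random-resized-crop area scale range (spatial deformation strength),
#' and the weak photometric distortion ranges shared across layers.
#'
#' @param patch_size central crop side length in pixels.
#' @param view_size output view side length in pixels (<= `patch_size`).
#' @param area_scale_range length-2 numeric, fraction of patch area sampled by
#'   the random resized crop; `0 < low <= high <= 1`.
#' @param aspect_range length-2 numeric aspect-ratio range (log-uniform).
#' @param photometric list with `contrast_range`, `luminance_range`,
#'   `noise_sigma_range` (each length 2).
#' @param mode `"rrc"` (random resized crop), `"none"` (plain resize of the
#'   patch, deformation strength 0), or `"nonoverlap"` (two disjoint-support
#'   crops, for the ablation grid).
#' @return Object of class `augment_spec`.
#' @export
augment_spec <- function(patch_size, view_size,
                         area_scale_range = c(0.6, 0.9),
                         aspect_range = c(3 / 4, 4 / 3),
                         photometric = default_photometric(),
                         mode = c("rrc", "none", "nonoverlap")) {
  mode <- match.arg(mode)
  if (view_size > patch_size) stopf("view_size must be <= patch_size")
  a <- area_scale_range
  if (!(a[1] > 0 && a[1] <= a[2] && a[2] <= 1)) {
    stopf("area_scale_range must satisfy 0 < low <= high <= 1")
  }
  if (aspect_range[1] <= 0 || aspect_range[1] > aspect_range[2]) {
    stopf("invalid aspect_range")
  }
  for (nm in c("contrast_range", "luminance_range", "noise_sigma_range")) {
    if (is.null(photometric[[nm]]) || length(photometric[[nm]]) != 2) {
      stopf("photometric$%s must have length 2", nm)
    }
  }
  if (any(photometric$noise_sigma_range < 0)) stopf("noise sigma must be non-negative")
  structure(list(patch_size = as.integer(patch_size),
                 view_size = as.integer(view_size),
                 area_scale_range = a, aspect_range = aspect_range,
                 photometric = photometric, mode = mode),
            class = "augment_spec")
}

#' @rdname augment_spec
#' @export
default_photometric <- function() {
  list(contrast_range = c(0.8, 1.2),
       luminance_range = c(-0.1, 0.1),
       noise_sigma_range = c(0, 0.05))
}

#' Central crop
#'
#' Extracts the centred `size` x `size` window; the offset along each axis is
#' `floor((dim - size) / 2)`.
#'
#' @param image numeric matrix.
#' @param size crop side length (<= both image dimensions).
#' @return `size` x `size` matrix.
#' @export
central_crop <- function(image, size) {
  h <- nrow(image); w <- ncol(image)
  if (size > h || size > w) stopf("crop size %d exceeds image dimensions %dx%d", size, h, w)
  oy <- floor((h - size) / 2); ox <- floor((w - size) / 2)
  image[(oy + 1):(oy + size), (ox + 1):(ox + size), drop = FALSE]
}

# Sample one crop rectangle: area fraction uniform in area_scale_range and
# aspect ratio log-uniform in aspect_range restricted to its feasible
# sub-interval given the drawn area (so the area law is exact and unbiased,
# rather than rejection-biased), position uniform. If no aspect is feasible
# after bounded retries, fall back to the maximal centred crop (flagged).
sample_crop_rect <- function(h, w, area_scale_range, aspect_range, max_tries = 10) {
  area <- h * w
  q <- w / h
  for (k in seq_len(max_tries)) {
    frac <- stats::runif(1, area_scale_range[1], area_scale_range[2])
    lo <- max(aspect_range[1], q * frac)
    hi <- min(aspect_range[2], q / frac)
    if (lo > hi) next
    ar <- exp(stats::runif(1, log(lo), log(hi)))
    target <- frac * area
    cw <- min(w, max(1L, round(sqrt(target * ar))))
    ch <- min(h, max(1L, round(sqrt(target / ar))))
    x0 <- sample.int(w - cw + 1, 1)
    y0 <- sample.int(h - ch + 1, 1)
    return(list(y = y0, x = x0, h = ch, w = cw, frac = frac, fallback = FALSE))
  }
  side <- min(h, w)
  list(y = floor((h - side) / 2) + 1, x = floor((w - side) / 2) + 1,
       h = side, w = side, fallback = TRUE)
}

#' Random resized crop
#'
#' Samples a sub-rectangle of the patch whose area fraction is uniform in
#' `area_scale_range` and whose aspect ratio is log-uniform in `aspect_range`,
#' then resizes it to `view_size` x `view_size` with bilinear interpolation
#' (half-pixel-centre alignment). Uses R's global RNG stream; set the seed for
#' reproducibility. If no feasible rectangle is found within 10 tries, falls
#' back to the maximal centred crop (attribute `"fallback"`).
#'
#' @param patch numeric matrix in `[0, 1]`.
#' @param view_size output side length.
#' @param area_scale_range,aspect_range see [augment_spec()].
#' @return `view_size` x `view_size` matrix.
#' @export
random_resized_crop <- function(patch, view_size, area_scale_range = c(0.6, 0.9),
                                aspect_range = c(3 / 4, 4 / 3)) {
  r <- sample_crop_rect(nrow(patch), ncol(patch), area_scale_range, aspect_range)
  sub <- patch[r$y:(r$y + r$h - 1), r$x:(r$x + r$w - 1), drop = FALSE]
  out <- bilinear_resize(sub, view_size, view_size)
  if (r$fallback) attr(out, "fallback") <- TRUE
  out
}

#' Weak photometric distortion
#'
#' Applies multiplicative contrast about the view mean, an additive luminance
#' shift, and additive Gaussian pixel noise with a standard deviation drawn
#' uniformly from `noise_sigma_range`; the result is clipped to `[0, 1]`.
#'
#' @param view numeric matrix in `[0, 1]`.
#' @param photometric list as in [augment_spec()].
#' @return Distorted view, same dimensions.
#' @export
photometric_distort <- function(view, photometric = default_photometric()) {
  cr <- stats::runif(1, photometric$contrast_range[1], photometric$contrast_range[2])
  lu <- stats::runif(1, photometric$luminance_range[1], photometric$luminance_range[2])
  sg <- stats::runif(1, photometric$noise_sigma_range[1], photometric$noise_sigma_range[2])
  m <- mean(view)
  out <- (view - m) * cr + m + lu
  if (sg > 0) out <- out + matrix(stats::rnorm(length(view), 0, sg), nrow(view))
  clip01(out)
}

# Two crops with provably disjoint support: the patch is split in half along a
# random axis and one crop is sampled inside each half.
nonoverlap_rects <- function(h, w, area_scale_range, aspect_range) {
  if (stats::runif(1) < 0.5) {
    top <- sample_crop_rect(floor(h / 2), w, area_scale_range, aspect_range)
    bot <- sample_crop_rect(h - ceiling(h / 2), w, area_scale_range, aspect_range)
    bot$y <- bot$y + ceiling(h / 2)
    list(top, bot)
  } else {
    lef <- sample_crop_rect(h, floor(w / 2), area_scale_range, aspect_range)
    rig <- sample_crop_rect(h, w - ceiling(w / 2), area_scale_range, aspect_range)
    rig$x <- rig$x + ceiling(w / 2)
    list(lef, rig)
  }
}

#' Generate an augmented view pair
#'
#' Centrally crops `spec$patch_size` from the image, then draws two
#' independently augmented views of the patch according to `spec$mode`:
#' random resized crops (`"rrc"`), plain resizes (`"none"`), or two
#' disjoint-support crops (`"nonoverlap"`). Photometric distortion is applied
#' to both views.
#'
#' @param image numeric matrix, at least `spec$patch_size` on each side.
#' @param spec an [augment_spec()].
#' @return List with elements `A` and `B`, each `view_size` x `view_size`.
#' @export
make_view_pair <- function(image, spec) {
  stopifnot(inherits(spec, "augment_spec"))
  patch <- central_crop(image, spec$patch_size)
  one <- function(rect = NULL) {
    v <- if (spec$mode == "none") {
      bilinear_resize(patch, spec$view_size, spec$view_size)
    } else if (!is.null(rect)) {
      bilinear_resize(patch[rect$y:(rect$y + rect$h - 1),
                            rect$x:(rect$x + rect$w - 1), drop = FALSE],
                      spec$view_size, spec$view_size)
    } else {
      random_resized_crop(patch, spec$view_size, spec$area_scale_range,
                          spec$aspect_range)
    }
    photometric_distort(v, spec$photometric)
  }
  if (spec$mode == "nonoverlap") {
    rr <- nonoverlap_rects(nrow(patch), ncol(patch), spec$area_scale_range,
                           spec$aspect_range)
    list(A = one(rr[[1]]), B = one(rr[[2]]))
  } else {
    list(A = one(), B = one())
  }
}

#' Default complexity schedule
#'
#' The two-layer schedule in which both the patch/view sizes and the
#' deformation range are scaled by a factor of 2 between layers, matching the
#' approximate doubling of receptive field size between cortical areas V1 and
#' V2: layer 1 crops a 56 px patch and produces 48 px views with crop scale
#' (0.6, 0.9); layer 2 crops 112 px and produces 96 px views with scale
#' (0.3, 0.9). Photometric parameters are shared.
#'
#' @param photometric shared photometric parameter list.
#' @return Object of class `complexity_schedule`: list of per-layer
#'   [augment_spec()]s plus the `scale_factor`.
#' @export
default_schedule <- function(photometric = default_photometric()) {
  sch <- structure(list(
    layers = list(
      augment_spec(56, 48, c(0.6, 0.9), photometric = photometric),
      augment_spec(112, 96, c(0.3, 0.9), photometric = photometric)
    ),
    scale_factor = 2
  ), class = "complexity_schedule")
  validate_schedule(sch)
  sch
}

#' @rdname default_schedule
#' @param schedule a `complexity_schedule` to validate.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "complexity_schedule"))
  ls <- schedule$layers
  sf <- schedule$scale_factor
  for (l in seq_along(ls)[-1]) {
    a <- ls[[l - 1]]; b <- ls[[l]]
    if (b$patch_size != sf * a$patch_size || b$view_size != sf * a$view_size) {
      stopf("layer %d patch/view sizes are not %gx layer %d's", l, sf, l - 1)
    }
    if (abs(a$area_scale_range[1] / b$area_scale_range[1] - sf) > 1e-9) {
      stopf("layer %d minimum area scale is not layer %d's divided by %g", l, l - 1, sf)
    }
  }
  invisible(schedule)
}

#' Spatial deformation strength ladder
#'
#' The graded set of spatial deformation strengths used in the
#' complexity-mismatch ablation grid: strength 0 is no spatial deformation
#' (plain resize), strengths 1-3 are random resized crops with minimum area
#' scales 0.6, 0.3 and 0.08 (maximum held at 0.9), and `"nonoverlap"` forces
#' two disjoint-support crops.
#'
#' @return Named list of ladder entries, each with `mode` and
#'   `area_scale_range`.
#' @export
deformation_strength_ladder <- function() {
  list(
    `0` = list(mode = "none", area_scale_range = c(1, 1)),
    `1` = list(mode = "rrc", area_scale_range = c(0.6, 0.9)),
    `2` = list(mode = "rrc", area_scale_range = c(0.3, 0.9)),
    `3` = list(mode = "rrc", area_scale_range = c(0.08, 0.9)),
    nonoverlap = list(mode = "nonoverlap", area_scale_range = c(0.08, 0.45))
  )
}
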