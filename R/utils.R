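#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
# All generator functions route their randomness through this so that a given
# seed yields bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a parent seed and an index, staying within the
# 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 31 + as.numeric(p)) %% 2147483647
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Bilinear sampling at fractional coordinates with half-pixel-centre
# (align-corners = FALSE) semantics: output pixel centre k + 0.5 maps to input
# coordinate (k + 0.5) * scale. Edge samples are clamped.
bilinear_resize <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  if (in_h == out_h && in_w == out_w) return(img)
  sy <- in_h / out_h; sx <- in_w / out_w
  yc <- ((seq_len(out_h) - 0.5) * sy) - 0.5
  xc <- ((seq_len(out_w) - 0.5) * sx) - 0.5
  yc <- pmin(pmax(yc, 0), in_h - 1)
  xc <- pmin(pmax(xc, 0), in_w - 1)
  y0 <- pmin(floor(yc), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(floor(xc), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- yc - y0; wx <- xc - x0
  a <- img[y0 + 1, x0 + 1, drop = FALSE]
  b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c2 <- img[y1 + 1, x0 + 1, drop = FALSE]
  d <- img[y1 + 1, x1 + 1, drop = FALSE]
  wyM <- matrix(wy, out_h, out_w)
  wxM <- matrix(wx, out_h, out_w, byrow = TRUE)
  a * (1 - wyM) * (1 - wxM) + b * (1 - wyM) * wxM +
    c2 * wyM * (1 - wxM) + d * wyM * wxM
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
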