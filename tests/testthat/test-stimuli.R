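test_that("stimulus set has the full factorial design with paired conditions", {
  ss <- v2_stimuli()
  expect_s3_class(ss, "stimulus_set")
  expect_equal(dim(ss$images), c(64, 64, 450))
  expect_equal(nrow(ss$meta), 450)
  expect_equal(sum(ss$meta$condition == "texture"), 225)
  # texture/noise pairing is a bijection over (family, sample)
  tex <- ss$meta[ss$meta$condition == "texture", c("family_id", "sample_id")]
  noi <- ss$meta[ss$meta$condition == "noise", c("family_id", "sample_id")]
  expect_equal(tex[order(tex$family_id, tex$sample_id), ],
               noi[order(noi$family_id, noi$sample_id), ],
               ignore_attr = TRUE)
  expect_true(all(ss$images >= 0 & ss$images <= 1))
})

test_that("stimulus set counts follow the requested design", {
  s11 <- build_v2_stimulus_set(1, 1, 64, rng_seed = 1)
  expect_equal(dim(s11$images)[3], 2)
  expect_setequal(s11$meta$condition, c("texture", "noise"))
  s34 <- build_v2_stimulus_set(3, 4, 64, rng_seed = 1)
  expect_equal(dim(s34$images)[3], 24)
  expect_equal(sum(s34$meta$condition == "texture"), 12)
})

test_that("texture generation is bit-reproducible and size-checked", {
  spec <- texture_family_spec(orientation = 0.4, seed = 5)
  a <- make_texture_family(spec, 3, 64, rng_seed = 9)
  b <- make_texture_family(spec, 3, 64, rng_seed = 9)
  expect_identical(a, b)
  c2 <- make_texture_family(spec, 3, 64, rng_seed = 10)
  expect_false(identical(a, c2))
  expect_error(make_texture_family(spec, 3, 16), "size")
  expect_error(make_texture_family(texture_family_spec(freq = 30), 2, 64),
               "frequency")
})

test_that("orientation bandwidth shapes the oriented-energy profile", {
  # independent oracle: a small bank of oriented Gaussian frequency filters
  oriented_energy <- function(img, theta) {
    n <- nrow(img)
    w <- lcml:::fft_freqs(n)
    WX <- matrix(w, n, n, byrow = TRUE); WY <- matrix(w, n, n)
    th <- atan2(WY, WX); r <- sqrt(WX^2 + WY^2)
    d <- atan2(sin(2 * (th - theta)), cos(2 * (th - theta))) / 2
    filt <- exp(-d^2 / (2 * 0.3^2)) * (r > 0.3 & r < 2.5)
    sum(Mod(stats::fft(img))^2 * filt)
  }
  narrow <- texture_family_spec(orientation = 0, orientation_bw = 0.15, seed = 3)
  wide <- texture_family_spec(orientation = 0, orientation_bw = 1.2, seed = 3)
  ratio <- function(spec) {
    imgs <- make_texture_family(spec, 5, 64, rng_seed = 2)
    e0 <- mean(sapply(imgs, oriented_energy, theta = 0))
    e90 <- mean(sapply(imgs, oriented_energy, theta = pi / 2))
    e0 / e90
  }
  expect_gt(ratio(narrow), ratio(wide))
  expect_gt(ratio(narrow), 2)
})

test_that("spectral matching preserves the amplitude spectrum exactly before clipping", {
  ss <- v2_stimuli()
  for (i in c(1, 101, 301)) {
    im <- ss$images[, , i]
    nz <- spectral_match_noise(im, rng_seed = i)
    u <- attr(nz, "unclipped")
    expect_lt(max(abs(Mod(stats::fft(im)) - Mod(stats::fft(u)))), 1e-6)
    expect_equal(mean(u), mean(im), tolerance = 1e-12)
    expect_true(attr(nz, "clip_fraction") <= 0.05)
    expect_true(all(nz >= 0 & nz <= 1))
  }
})

test_that("spectral matching handles degenerate and structured inputs", {
  cst <- matrix(0.4, 32, 32)
  expect_equal(max(abs(spectral_match_noise(cst, 3) - 0.4)), 0)
  # pure sinusoid: output is a sinusoid of the same frequency and amplitude
  s <- 0.5 + 0.3 * grating(64, 5)
  sn <- attr(spectral_match_noise(s, 1), "unclipped")
  A1 <- Mod(stats::fft(s)); A2 <- Mod(stats::fft(sn))
  expect_lt(max(abs(A1 - A2)), 1e-9)
  # support unchanged: only DC and the +/-5 cycle bins are non-zero
  expect_equal(sum(A2 > 1e-6), sum(A1 > 1e-6))
  bad <- matrix(1, 8, 8); bad[2, 2] <- NA
  expect_error(spectral_match_noise(bad), "non-finite")
})

test_that("training corpus has natural-like spectral statistics", {
  corpus <- tiny_corpus()
  expect_equal(dim(corpus), c(128, 128, 20))
  expect_true(all(corpus >= 0 & corpus <= 1))
  # radially averaged power spectrum slope on log-log axes
  slope_of <- function(img) {
    n <- nrow(img)
    P <- Mod(stats::fft(img - mean(img)))^2
    w <- lcml:::fft_freqs(n)
    r <- sqrt(outer(w^2, w^2, "+"))
    bins <- cut(as.vector(r), breaks = 2 * pi * c(2, 4, 8, 16, 32, 48) / n)
    pw <- tapply(as.vector(P), bins, mean)
    fr <- tapply(as.vector(r), bins, mean)
    stats::coef(stats::lm(log(pw) ~ log(fr)))[2]
  }
  slopes <- sapply(1:10, function(i) slope_of(corpus[, , i]))
  expect_true(all(slopes > -2.5 & slopes < -1.5))
  # seed change produces different images
  corpus2 <- make_training_corpus(2, size = 128, rng_seed = 22)
  expect_false(identical(corpus[, , 1], corpus2[, , 1]))
})

test_that("stimulus sets round-trip through 16-bit files and CSV metadata", {
  ss <- build_v2_stimulus_set(2, 2, 64, rng_seed = 4)
  dir <- withr::local_tempdir()
  write_stimulus_set(ss, dir)
  back <- read_stimulus_set(dir)
  expect_equal(back$meta, ss$meta, ignore_attr = TRUE)
  expect_lt(max(abs(back$images - ss$images)), 2^-15)
})
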