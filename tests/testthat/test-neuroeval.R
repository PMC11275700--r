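test_that("simulated neurons have the canonical shape and analytic modulation", {
  ss <- v2_stimuli()
  nd <- simulate_v2_neurons(ss, 103, "metadata", rng_seed = 3)
  expect_s3_class(nd, "neural_dataset")
  expect_equal(dim(nd$responses), c(103, 450))
  expect_true(all(nd$responses >= 0))
  expect_identical(simulate_v2_neurons(ss, 103, "metadata", rng_seed = 3)$responses,
                   nd$responses)
  # noise-free: Rmod equals g / (2b + g) exactly
  nd0 <- simulate_v2_neurons(ss, 20, "metadata", noise_sd = 0, rng_seed = 4)
  mt <- modulation_index(nd0)
  expect_lt(max(abs(mt$rmod - nd0$ground_truth$rmod_true)), 1e-12)
})

test_that("modulation index evaluates its formula and aggregates consistently", {
  meta <- data.frame(family_id = rep(1:2, each = 4),
                     sample_id = rep(1:2, times = 4),
                     condition = rep(c("texture", "texture", "noise", "noise"), 2))
  eq <- list(responses = matrix(2, 3, 8), meta = meta)
  expect_true(all(modulation_index(eq)$rmod == 0))
  r <- matrix(0, 1, 8)
  r[meta$condition == "texture"] <- 5
  expect_true(all(modulation_index(list(responses = r, meta = meta))$rmod == 1))
  r2 <- matrix(1, 1, 8)
  r2[meta$condition == "texture"] <- 3
  expect_true(all(modulation_index(list(responses = r2, meta = meta))$rmod == 0.5))
  # undefined pairs are excluded and counted
  r3 <- matrix(1, 1, 8); r3[1, meta$family_id == 2] <- 0
  m3 <- modulation_index(list(responses = r3, meta = meta))
  expect_true(is.na(m3$rmod[1, 2]))
  expect_equal(attr(m3, "n_undefined"), 1)
  expect_equal(m3$per_neuron[1], 0)   # average over defined families only
  # aggregate consistency and bounds on simulated data
  nd <- simulate_v2_neurons(v2_stimuli(), 30, "metadata", rng_seed = 5)
  mt <- modulation_index(nd)
  expect_true(all(mt$rmod >= -1 & mt$rmod <= 1, na.rm = TRUE))
  expect_lt(max(abs(mt$per_neuron - rowMeans(mt$rmod, na.rm = TRUE))), 1e-12)
  expect_lt(max(abs(mt$per_family - colMeans(mt$rmod, na.rm = TRUE))), 1e-12)
})

test_that("estimated modulation converges to the analytic value at low noise", {
  # 100 samples per family, noise sd = 1% of typical baseline
  ss <- build_v2_stimulus_set(2, 100, 32, rng_seed = 6)
  nd <- simulate_v2_neurons(ss, 25, "metadata", noise_sd = 0.1, rng_seed = 7)
  mt <- modulation_index(nd)
  expect_lt(max(abs(mt$rmod - nd$ground_truth$rmod_true)), 0.02)
})

test_that("PLS predictivity recovers feature-driven neurons and rejects noise", {
  ss <- v2_stimuli()
  set.seed(8)
  basis <- matrix(rnorm(450 * 20), 450)
  ndf <- simulate_v2_neurons(ss, 103, "feature", noise_sd = 1e-8,
                             feature_basis = basis, rng_seed = 9)
  pr <- fit_pls_predictivity(basis, ndf, n_components = 25, n_folds = 10,
                             rng_seed = 10)
  expect_gte(pr$median_ev, 0.95)
  # pure-noise neurons are at chance
  noise_resp <- matrix(abs(rnorm(103 * 450, 10, 2)), 103)
  prn <- fit_pls_predictivity(basis, noise_resp, n_components = 25,
                              n_folds = 10, rng_seed = 11)
  expect_lte(prn$median_ev, 0.05)
  # duplicating every feature column leaves scores unchanged
  pr2 <- fit_pls_predictivity(cbind(basis, basis), ndf, n_components = 25,
                              n_folds = 10, rng_seed = 10)
  expect_lt(max(abs(pr2$per_neuron - pr$per_neuron)), 1e-6)
})

test_that("predictivity degrades monotonically with response noise", {
  ss <- build_v2_stimulus_set(5, 15, 64, rng_seed = 12)
  set.seed(13)
  basis <- matrix(rnorm(150 * 20), 150)
  evs <- sapply(c(0.01, 0.3, 1, 3), function(sdl) {
    nd <- simulate_v2_neurons(ss, 30, "feature", noise_sd = sdl,
                              feature_basis = basis, rng_seed = 14)
    fit_pls_predictivity(basis, nd, n_components = 15, n_folds = 5,
                         rng_seed = 15)$median_ev
  })
  expect_true(all(diff(evs) <= 0))
})

test_that("PLS agrees with independent implementations where they coincide", {
  set.seed(16)
  X <- matrix(rnorm(60 * 12), 60); colnames(X) <- paste0("f", 1:12)
  # multi-response at full rank: PLS regression equals ordinary least squares
  Y <- X %*% matrix(rnorm(12 * 4), 12) + matrix(rnorm(60 * 4, 0, 0.1), 60)
  pred_full <- lcml:::simpls_predict(lcml:::simpls_fit(X, Y, 12), X)
  ols <- cbind(1, X) %*% stats::coef(stats::lm(Y ~ X))
  expect_lt(max(abs(pred_full - ols)), 1e-8)
  # single response at reduced rank: SIMPLS and NIPALS PLS1 coincide
  skip_if_not_installed("mixOmics")
  y <- X %*% rnorm(12) + rnorm(60, 0, 0.1)
  pred1 <- lcml:::simpls_predict(lcml:::simpls_fit(X, cbind(y), 5), X)
  mo <- mixOmics::pls(X, cbind(y), ncomp = 5, mode = "regression", scale = FALSE)
  pmo <- predict(mo, X)$predict[, , 5]
  expect_lt(max(abs(pred1 - pmo)), 1e-8)
})

test_that("best-layer selection follows the validation protocol", {
  mk <- function(med) structure(list(median_ev = med), class = "pls_predictivity")
  expect_equal(select_best_layer(list(mk(0.3))), 1)
  expect_equal(select_best_layer(list(mk(0.5), mk(0.2))), 1)  # A wins validation
  expect_equal(select_best_layer(list(mk(0.2), mk(0.5))), 2)
  expect_equal(select_best_layer(list(mk(0.4), mk(0.4))), 1)  # tie -> lower index
})

test_that("quartile partition sizes and ordering are correct", {
  set.seed(17)
  p103 <- partition_neurons(runif(103))
  expect_equal(length(p103$v1_like), 26)
  expect_equal(length(p103$v2_like), 26)
  p8 <- partition_neurons(runif(8))
  expect_equal(lengths(p8), c(v1_like = 2L, v2_like = 2L))
  inc <- partition_neurons(seq_len(20) / 20)
  expect_equal(inc$v1_like, 16:20)
  expect_equal(inc$v2_like, 1:5)
})

test_that("Q-Q comparison matches location shifts and analytic quantiles", {
  set.seed(18)
  x <- rnorm(400)
  same <- qq_compare(x, x)
  expect_equal(same$max_deviation, 0)
  sh <- qq_compare(x, x + 0.2)
  expect_equal(max(abs(sh$model_q - sh$reference_q)), 0.2, tolerance = 1e-12)
  # two Betas: empirical quantile gaps match the analytic difference
  a <- rbeta(20000, 2, 5); b <- rbeta(20000, 5, 2)
  qq <- qq_compare(a, b, n_quantiles = 9)
  analytic <- qbeta(qq$probs, 2, 5) - qbeta(qq$probs, 5, 2)
  expect_lt(max(abs((qq$model_q - qq$reference_q) - analytic)), 0.02)
})

test_that("Spearman rank comparison matches the closed form", {
  # hand-workable T=5 case
  m <- c(10, 20, 15, 40, 30); r <- c(1, 3, 2, 5, 4)
  fr <- family_rank_compare(m, r)
  d <- rank(m) - rank(r)
  expect_equal(fr$rho, 1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)
  expect_equal(family_rank_compare(1:15, 1:15)$rho, 1)
  expect_equal(family_rank_compare(1:15, 15:1)$rho, -1)
  # exhaustive enumeration over all tie-free T=4 permutations
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    d <- p - 1:4
    expect_equal(family_rank_compare(as.numeric(p), 1:4)$rho,
                 1 - 6 * sum(d^2) / (4 * 15), tolerance = 1e-12)
  }
  expect_true(is.na(family_rank_compare(rep(1, 5), 1:5)$rho))
})

test_that("bootstrap rank-difference test behaves sensibly", {
  set.seed(19)
  fam_effect <- seq(0.1, 0.9, length.out = 15)
  ref_tab <- outer(rep(1, 60), fam_effect) + matrix(rnorm(60 * 15, 0, 0.05), 60)
  mod_tab <- outer(rep(1, 60), fam_effect) + matrix(rnorm(60 * 15, 0, 0.05), 60)
  cmp_tab <- matrix(rnorm(60 * 15, 0.5, 0.3), 60)   # unrelated to the families
  fr <- family_rank_compare(colMeans(mod_tab), colMeans(ref_tab),
                            competitor = colMeans(cmp_tab),
                            model_table = mod_tab, competitor_table = cmp_tab,
                            reference_table = ref_tab,
                            n_bootstrap = 1000, rng_seed = 20)
  expect_gt(fr$rho, 0.9)
  expect_true(fr$p_value >= 0 && fr$p_value <= 1)
  expect_lt(fr$p_value, 0.05)   # aligned model beats an unrelated competitor
})

test_that("relative improvement reproduces the behavioral metric", {
  expect_equal(round(relative_improvement(0.211, 0.165)), 28)
  expect_equal(relative_improvement(0.4, 0.4), 0)
  expect_equal(relative_improvement(2, 1), 100)
  expect_error(relative_improvement(0.2, 0), "positive")
})
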