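test_that("cross-correlation matches its definition and bounds", {
  # identity-pattern batch: orthonormal columns give C = I
  z <- diag(5)
  expect_equal(cross_correlation(z, z), diag(5))
  set.seed(1)
  zA <- matrix(rnorm(8 * 5), 8)
  expect_equal(diag(cross_correlation(zA, -zA)), rep(-1, 5))
  # brute-force double-loop oracle
  zB <- matrix(rnorm(8 * 5), 8)
  for (cen in c(FALSE, TRUE)) {
    a <- zA; b <- zB
    if (cen) { a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b)) }
    Co <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      Co[i, j] <- sum(a[, i] * b[, j]) /
        (sqrt(sum(a[, i]^2)) * sqrt(sum(b[, j]^2)))
    }
    expect_lt(max(abs(cross_correlation(zA, zB, center = cen) - Co)), 1e-10)
  }
  # Cauchy-Schwarz bounds across random draws
  for (s in 1:20) {
    set.seed(s)
    C <- cross_correlation(matrix(rnorm(12 * 6), 12), matrix(rnorm(12 * 6), 12))
    expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
  }
  zz <- zA; zz[, 3] <- 0
  expect_error(cross_correlation(zz, zB), "3")
})

test_that("Barlow loss evaluates its formula and is zero only at identity", {
  expect_equal(barlow_loss(diag(7)), 0)
  expect_equal(barlow_loss(matrix(0, 4, 4)), 4)   # sum_i 1^2 = D
  C <- diag(c(0.5, 1, 1)); C[1, 2] <- 0.2
  expect_equal(barlow_loss(C, lambda = 0.005), 0.25 + 0.005 * 0.04)
  # gradient descent on toy embeddings drives C to the identity
  set.seed(2)
  zA <- matrix(rnorm(6 * 4), 6); zB <- zA + matrix(rnorm(6 * 4, 0, 0.3), 6)
  for (it in 1:4000) {
    g <- lcml:::barlow_grad(zA, zB, lambda = 0.05)
    zA <- zA - 0.05 * g$dzA
    zB <- zB - 0.05 * g$dzB
  }
  Cend <- cross_correlation(zA, zB)
  expect_lt(barlow_loss(Cend, 0.05), 1e-3)
  expect_lt(max(abs(Cend - diag(4))), 0.05)
})

test_that("loss gradients match finite differences", {
  set.seed(3)
  zA <- matrix(rnorm(8 * 5), 8); zB <- matrix(rnorm(8 * 5), 8)
  for (cen in c(FALSE, TRUE)) {
    g <- lcml:::barlow_grad(zA, zB, 0.005, cen)
    fd <- num_grad(function(z) barlow_loss(cross_correlation(matrix(z, 8), zB, cen), 0.005),
                   as.vector(zA))
    expect_lt(max(abs(fd - as.vector(g$dzA))), 1e-6)
  }
  g <- lcml:::sample_contrastive_grad(zA, zB, 0.1)
  fd <- num_grad(function(z) sample_contrastive_loss(matrix(z, 8), zB, 0.1),
                 as.vector(zA))
  expect_lt(max(abs(fd - as.vector(g$dzA))), 1e-6)
})

test_that("layerwise loss is an additive, order-invariant sum", {
  set.seed(4)
  e1 <- list(A = matrix(rnorm(8 * 4), 8), B = matrix(rnorm(8 * 4), 8))
  e2 <- list(A = matrix(rnorm(8 * 4), 8), B = matrix(rnorm(8 * 4), 8))
  ll <- layerwise_loss(list(e1, e2))
  l1 <- barlow_loss(cross_correlation(e1$A, e1$B))
  l2 <- barlow_loss(cross_correlation(e2$A, e2$B))
  expect_equal(ll$total, l1 + l2, tolerance = 1e-12)
  expect_equal(ll$per_layer, c(l1, l2))
  expect_equal(layerwise_loss(list(e2, e1))$total, ll$total)
  # both layers at the exact minimum
  id <- list(A = diag(4), B = diag(4))
  expect_equal(layerwise_loss(list(id, id))$total, 0)
})

test_that("sample-contrastive loss matches closed form and enumeration", {
  tau <- 0.1
  # N=2, orthogonal unit embeddings, positives identical
  zA <- diag(2); zB <- diag(2)
  expected <- -log(exp(1 / tau) / (exp(1 / tau) + 2 * exp(0)))
  expect_equal(sample_contrastive_loss(zA, zB, tau), expected, tolerance = 1e-12)
  # invariance to a common rotation
  set.seed(5)
  zA <- matrix(rnorm(6 * 4), 6); zB <- matrix(rnorm(6 * 4), 6)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  expect_equal(sample_contrastive_loss(zA %*% Q, zB %*% Q, tau),
               sample_contrastive_loss(zA, zB, tau), tolerance = 1e-10)
  # brute-force enumeration oracle
  n <- 4
  zA <- matrix(rnorm(n * 3), n); zB <- matrix(rnorm(n * 3), n)
  z <- rbind(zA, zB); z <- z / sqrt(rowSums(z^2))
  pos <- c((n + 1):(2 * n), 1:n)
  tot <- 0
  for (u in 1:(2 * n)) {
    s <- sapply(1:(2 * n), function(v) sum(z[u, ] * z[v, ]) / tau)
    tot <- tot - log(exp(s[pos[u]]) / sum(exp(s[-u])))
  }
  expect_equal(sample_contrastive_loss(zA, zB, tau), tot / (2 * n),
               tolerance = 1e-8)
})

test_that("non-contrastive loss honours the stop-gradient contract", {
  set.seed(6)
  zA <- matrix(rnorm(8 * 5), 8)
  idp <- simsiam_predictor(5, 0)
  expect_equal(noncontrastive_loss(zA, zA, idp), -1, tolerance = 1e-12)
  orthB <- matrix(0, 4, 5); orthB[, 5] <- 1
  expect_equal(noncontrastive_loss(cbind(diag(4), 0), orthB, idp), 0,
               tolerance = 1e-12)
  # gradients flow only through the predictor branch of each term
  zB <- matrix(rnorm(8 * 5), 8)
  pr <- simsiam_predictor(5, 8, init_seed = 7)
  g <- lcml:::noncontrastive_grad(zA, zB, pr)
  mcos <- function(P, T_) mean(rowSums(P * T_) / (sqrt(rowSums(P^2)) * sqrt(rowSums(T_^2))))
  fwd <- function(z) lcml:::predictor_forward(pr, z)$p
  fdA <- num_grad(function(z) -0.5 * mcos(fwd(matrix(z, 8)), zB), as.vector(zA))
  expect_lt(max(abs(fdA - as.vector(g$dzA))), 1e-6)
  # the blocked branch contributes exactly nothing: perturbing the target of
  # term 1 leaves dzA's analytic value unchanged
  g2 <- lcml:::noncontrastive_grad(zA, zB + 0, pr)
  expect_identical(g$dzA, g2$dzA)
  # full-loss finite differences (which see both branches) must NOT match
  fd_full <- num_grad(function(z) noncontrastive_loss(matrix(z, 8), zB, pr),
                      as.vector(zA))
  expect_gt(max(abs(fd_full - as.vector(g$dzA))), 1e-4)
})

test_that("losses are permutation-equivariant over the batch", {
  set.seed(8)
  zA <- matrix(rnorm(10 * 6), 10); zB <- matrix(rnorm(10 * 6), 10)
  p <- sample(10)
  expect_equal(barlow_loss(cross_correlation(zA[p, ], zB[p, ])),
               barlow_loss(cross_correlation(zA, zB)), tolerance = 1e-12)
  expect_equal(sample_contrastive_loss(zA[p, ], zB[p, ]),
               sample_contrastive_loss(zA, zB), tolerance = 1e-12)
  pr <- simsiam_predictor(6, 8, 1)
  expect_equal(noncontrastive_loss(zA[p, ], zB[p, ], pr),
               noncontrastive_loss(zA, zB, pr), tolerance = 1e-12)
})
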