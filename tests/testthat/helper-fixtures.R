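# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# central-difference numeric gradient
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# the full texture/noise stimulus design
v2_stimuli <- function() memo("v2_stimuli", build_v2_stimulus_set(15, 15, 64, rng_seed = 11))

# small training corpus for quick trainer tests
tiny_corpus <- function() memo("tiny_corpus", make_training_corpus(20, size = 128, rng_seed = 21))

# the smoke-training fit: 200 synthetic images, 20 epochs, fixed seed
smoke_corpus <- function() memo("smoke_corpus", make_training_corpus(200, size = 128, rng_seed = 42))

smoke_fit <- function() {
  memo("smoke_fit",
       lcml_train(smoke_corpus(),
                  config = train_config(max_epochs = 20, stop_patience = 20,
                                        seed = 7)))
}

# horizontal full-field grating (varies along x), frequency in cycles/image
grating <- function(n, freq, phase = 0, theta = 0) {
  xs <- (0:(n - 1)) / n
  xm <- matrix(xs, n, n, byrow = TRUE)
  ym <- matrix(xs, n, n)
  cos(2 * pi * freq * (cos(theta) * xm + sin(theta) * ym) + phase)
}
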