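test_that("early stopping scans the validation sequence correctly", {
  # strictly and substantially decreasing: never stops
  dec <- 10 * 0.8^(0:14)
  expect_false(early_stop(dec, 1e-3, 5)$stop)
  # constant loss with patience 3 stops at evaluation 4
  cst <- early_stop(rep(2, 10), 1e-3, 3)
  expect_true(cst$stop)
  expect_equal(cst$stop_epoch, 4)
  # noisy-but-improving sequence: decision matches an independent scan
  set.seed(1)
  seqv <- 5 * 0.95^(0:29) + rnorm(30, 0, 0.02)
  ref_scan <- function(v, thr, pat) {
    best <- v[1]; wait <- 0
    for (i in seq_along(v)[-1]) {
      if ((best - v[i]) / abs(best) > thr) wait <- 0 else wait <- wait + 1
      if (wait >= pat) return(i)
      if (v[i] < best) best <- v[i]
    }
    NA_integer_
  }
  for (pat in c(2, 4)) {
    got <- early_stop(seqv, 1e-3, pat)
    expect_equal(got$stop_epoch, ref_scan(seqv, 1e-3, pat))
  }
  expect_error(early_stop(numeric(0)), "validation")
})

test_that("training is deterministic under a fixed seed", {
  cfg <- train_config(max_epochs = 2, batch_size = 10, seed = 77)
  f1 <- lcml_train(tiny_corpus(), config = cfg)
  f2 <- lcml_train(tiny_corpus(), config = cfg)
  expect_identical(f1$encoder, f2$encoder)
  expect_identical(f1$history, f2$history)
  f3 <- lcml_train(tiny_corpus(), config = train_config(max_epochs = 2,
                                                        batch_size = 10, seed = 78))
  expect_false(identical(f1$encoder$stage1$W, f3$encoder$stage1$W))
})

test_that("layer-2 loss sends exactly zero gradient to stage 1", {
  enc <- two_stage_encoder(init_seed = 5)
  corpus <- tiny_corpus()
  cfg <- train_config(seed = 6)
  sch <- default_schedule()
  set.seed(6)
  vb <- lcml:::make_view_batch(corpus, 1:6, sch$layers[[2]])
  lp <- lcml:::layer_pass(enc, 2, vb, cfg, "barlow", NULL)
  # the gradient list covers stage-2 and projector-2 parameters only;
  # stage-1 parameters receive the machine-zero gradient by construction
  expect_setequal(names(lp$grads),
                  c("W", "b", "gamma", "beta", "pW1", "pb1", "pW2", "pb2"))
  st <- adam_state <- lcml:::adam_init(lcml:::layer_params(enc, 2))
  upd <- lcml:::adam_step(lcml:::layer_params(lp$enc, 2), lp$grads, adam_state, 1)
  after <- lcml:::put_layer_params(lp$enc, 2, upd$params)$enc
  expect_identical(after$stage1$W, enc$stage1$W)
  expect_identical(after$stage1$b, enc$stage1$b)
  expect_identical(after$stage1$bn, enc$stage1$bn)   # incl. running stats
  expect_false(identical(after$stage2$W, enc$stage2$W))
})

test_that("history is internally consistent and losses stay finite", {
  fit <- lcml_train(tiny_corpus(), config = train_config(max_epochs = 3,
                                                         batch_size = 10, seed = 9))
  h <- fit$history
  expect_equal(h$train_total, h$train_l1 + h$train_l2, tolerance = 1e-12)
  expect_equal(h$val_total, h$val_l1 + h$val_l2, tolerance = 1e-12)
  expect_true(all(is.finite(unlist(h[, -1]))))
  expect_output(print(fit), "Layerwise")
  s <- summary(fit)
  expect_s3_class(s, "summary.lcml")
  expect_equal(unname(s$receptive_fields), c(19, 67))
})

test_that("alternative losses train without divergence", {
  for (fam in c("simclr", "simsiam")) {
    fit <- lcml_train(tiny_corpus(),
                      config = train_config(max_epochs = 1, batch_size = 10,
                                            seed = 10, loss = fam))
    expect_true(all(is.finite(unlist(fit$history[, c("train_l1", "train_l2")]))))
  }
  # sequential mode runs one phase per layer
  fs <- lcml_train(tiny_corpus(),
                   config = train_config(max_epochs = 1, batch_size = 10,
                                         seed = 11, mode = "sequential"))
  expect_setequal(unique(fs$history$phase), c("1", "2"))
})

test_that("smoke training reduces both layers' losses over 20 epochs", {
  fit <- smoke_fit()
  h <- fit$history
  expect_equal(nrow(h), 20)
  expect_lt(h$train_l1[nrow(h)], h$train_l1[1])
  expect_lt(h$train_l2[nrow(h)], h$train_l2[1])
  # trained features differ from an untrained encoder's
  img <- smoke_corpus()[, , 1]
  enc0 <- two_stage_encoder(init_seed = lcml:::derive_seed(7L, 1L))
  expect_false(isTRUE(all.equal(predict(fit, img, layer = 2),
                                extract_features(enc0, img, layer = 2))))
})

test_that("ablation grid is bookkept, seeded and idempotent", {
  corpus <- make_training_corpus(12, size = 128, rng_seed = 30)
  cache <- withr::local_tempdir()
  cfg <- train_config(max_epochs = 1, batch_size = 6, val_fraction = 0.2,
                      seed = 12)
  tab <- run_ablation_grid(corpus, patch_sizes = 112,
                           deformation_strengths = c("1", "2"),
                           losses = "barlow",
                           eval_fn = function(fit) fit$history$val_l2[1],
                           config = cfg, cache_dir = cache)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$error)))
  expect_true(all(file.exists(tab$checkpoint)))
  expect_equal(length(unique(tab$checkpoint)), 2)
  expect_false(any(is.na(tab$score)))
  # rerunning a completed grid reuses checkpoints and reproduces the table
  tab2 <- run_ablation_grid(corpus, patch_sizes = 112,
                            deformation_strengths = c("1", "2"),
                            losses = "barlow",
                            eval_fn = function(fit) fit$history$val_l2[1],
                            config = cfg, cache_dir = cache)
  expect_identical(tab, tab2)
})

test_that("training rejects corpora smaller than the largest patch", {
  small <- make_training_corpus(4, size = 64, rng_seed = 13)
  expect_error(lcml_train(small), "patch")
})
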