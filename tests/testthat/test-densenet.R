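# small helper: random separable volumes for capacity/training checks
toy_volumes <- function(n, sp = c(12L, 12L, 8L), channels = 3L, shift = 2,
                        seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n)
  inputs <- lapply(seq_len(n), function(i) {
    a <- array(rnorm(channels * prod(sp)), c(channels, sp))
    if (labels[i] == 1) {
      bx <- 3:(sp[1] - 2); by <- 3:(sp[2] - 2); bz <- 2:(sp[3] - 1)
      a[1, bx, by, bz] <- a[1, bx, by, bz] + shift
    }
    a
  })
  list(inputs = inputs, labels = labels)
}

test_that("channel trace follows the dense-block recurrence", {
  paper <- densenet_config(in_channels = 5, preset = "paper")
  expect_equal(unname(channel_trace(paper)),
               c(64L, 256L, 128L, 512L, 256L, 1024L, 512L, 1024L))
  # zero growth: constant except for compression floors
  zg <- densenet_config(init_features = 10, growth_rate = 0,
                        block_layers = c(2, 2, 2, 2), preset = "tiny")
  expect_equal(unname(channel_trace(zg)), c(10L, 10L, 5L, 5L, 2L, 2L, 1L, 1L))
  # hand-computed recurrence for the tiny preset
  tiny <- densenet_config(preset = "tiny")
  hand <- c(8, 8 + 2 * 4, floor(16 * .5), 8 + 2 * 4, floor(16 * .5),
            8 + 2 * 4, floor(16 * .5), 8 + 2 * 4)
  expect_equal(unname(channel_trace(tiny)), as.integer(hand))
})

test_that("forward pass satisfies shape and normalization contracts", {
  cfg <- densenet_config(in_channels = 3, init_features = 4, growth_rate = 2,
                         block_layers = c(1, 1, 1, 1))
  m <- build_model(cfg, seed = 2)
  inputs <- toy_volumes(2, sp = c(8L, 8L, 8L))$inputs
  lg <- predict_logits(m, inputs)
  expect_equal(dim(lg), c(2L, 2L))
  pr <- t(apply(lg, 1, rsipipe:::softmax))
  expect_equal(rowSums(pr), c(1, 1), tolerance = 1e-6)
  probs <- predict_proba(m, inputs)
  expect_true(all(probs >= 0 & probs <= 1 & is.finite(probs)))
})

test_that("scalar fusion uses the scalar and plain models reject it", {
  cfgf <- densenet_config(in_channels = 2, init_features = 4, growth_rate = 2,
                          block_layers = c(1, 1, 1, 1), scalar_fusion = TRUE)
  m <- build_model(cfgf, seed = 5)
  x <- array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  p1 <- predict_proba(m, list(x), scalars = 0.1)
  p2 <- predict_proba(m, list(x), scalars = 5)
  expect_false(isTRUE(all.equal(p1, p2)))
  cfg0 <- densenet_config(in_channels = 2, init_features = 4, growth_rate = 2,
                          block_layers = c(1, 1, 1, 1), scalar_fusion = FALSE)
  m0 <- build_model(cfg0, seed = 5)
  expect_error(rsipipe:::net_forward(m0, rsipipe:::input_matrix(x)$x,
                                     c(8L, 8L, 8L), scalar = 1),
               "scalar")
  expect_error(predict_proba(m, list(array(rnorm(3 * 8^3), c(3, 8, 8, 8))),
                             scalars = 1),
               "channels")
})

test_that("learning-rate schedule hits its endpoints", {
  expect_equal(lr_schedule(0, 10, 100, 1e-3), 0)
  expect_equal(lr_schedule(10, 10, 100, 1e-3), 1e-3)
  expect_lt(lr_schedule(100, 10, 100, 1e-3), 1e-9)
  mid <- lr_schedule(55, 10, 100, 1e-3)
  expect_equal(mid, 1e-3 * 0.5 * (1 + cos(pi * 45 / 90)))
})

test_that("training is deterministic under a fixed seed", {
  tv <- toy_volumes(16, sp = c(8L, 8L, 6L), seed = 3)
  cfg <- densenet_config(in_channels = 3, init_features = 4, growth_rate = 2,
                         block_layers = c(1, 1, 1, 1))
  tc <- train_config(total_epochs = 2, batch_size = 4, seed = 11)
  t1 <- train_classifier(tv$inputs, tv$labels, cfg, tc)
  t2 <- train_classifier(tv$inputs, tv$labels, cfg, tc)
  expect_equal(t1$history, t2$history)
  expect_equal(predict_proba(t1, tv$inputs), predict_proba(t2, tv$inputs))
  expect_gte(t1$best_epoch, 1)
  expect_lte(t1$best_epoch, 2)
})

test_that("a tiny model overfits a separable training set", {
  tv <- toy_volumes(40, sp = c(12L, 12L, 8L), shift = 2, seed = 7)
  cfg <- densenet_config(in_channels = 3, preset = "tiny")
  tc <- train_config(total_epochs = 10, batch_size = 8, seed = 2)
  tr <- train_classifier(tv$inputs, tv$labels, cfg, tc)
  p <- predict_proba(tr, tv$inputs)
  expect_equal(roc_auc(p, tv$labels), 1.0)
  expect_lte(tr$best_epoch, tc$total_epochs)
})

test_that("training loss decreases for most epochs on a fixed toy set", {
  drops <- 0L; total <- 0L
  for (seed in 1:3) {
    tv <- toy_volumes(16, sp = c(8L, 8L, 6L), shift = 3, seed = seed)
    cfg <- densenet_config(in_channels = 3, init_features = 4, growth_rate = 2,
                           block_layers = c(1, 1, 1, 1))
    # full-batch gradients keep the per-epoch loss sequence comparable
    tc <- train_config(total_epochs = 8, batch_size = 16, seed = seed)
    tr <- train_classifier(tv$inputs, tv$labels, cfg, tc)
    d <- diff(tr$history$train_loss)
    drops <- drops + sum(d <= 0)
    total <- total + length(d)
  }
  expect_gte(drops / total, 0.9)
})

test_that("checkpoints reload to identical predictions", {
  tv <- toy_volumes(12, sp = c(8L, 8L, 6L), seed = 9)
  cfg <- densenet_config(in_channels = 3, init_features = 4, growth_rate = 2,
                         block_layers = c(1, 1, 1, 1))
  tr <- train_classifier(tv$inputs, tv$labels, cfg,
                         train_config(total_epochs = 1, batch_size = 4, seed = 1))
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(tr, f)
  tr2 <- load_classifier(f)
  expect_identical(predict_proba(tr, tv$inputs), predict_proba(tr2, tv$inputs))
  # manual softmax of the raw scores reproduces the probabilities
  lg <- predict_logits(tr, tv$inputs)
  expect_equal(predict_proba(tr, tv$inputs),
               exp(lg[, 2]) / (exp(lg[, 1]) + exp(lg[, 2])),
               tolerance = 1e-12)
})

test_that("occlusion maps obey their closed-form special cases", {
  cfg <- densenet_config(in_channels = 2, init_features = 4, growth_rate = 2,
                         block_layers = c(1, 1, 1, 1))
  m <- build_model(cfg, seed = 4)
  sp <- c(8L, 8L, 8L)
  # constant input: occluding with the channel mean changes nothing
  xconst <- array(rep(c(1, -2), prod(sp)), c(2, sp))
  hm <- occlusion_sensitivity(m, xconst, patch_size = 4, stride = 4)
  expect_equal(dim(hm), sp)
  expect_equal(max(abs(hm)), 0)
  # single whole-volume patch equals the direct two-pass difference
  set.seed(8)
  x <- array(rnorm(2 * prod(sp)), c(2, sp))
  hm1 <- occlusion_sensitivity(m, x, patch_size = 8, stride = 8)
  mi <- rsipipe:::input_matrix(x)
  base_p <- rsipipe:::softmax(rsipipe:::net_forward(m, mi$x, sp)$logits)[2]
  xo <- mi$x
  xo[] <- matrix(colMeans(mi$x), nrow(xo), 2, byrow = TRUE)
  p_occ <- rsipipe:::softmax(rsipipe:::net_forward(m, xo, sp)$logits)[2]
  expect_equal(unique(as.vector(hm1)), base_p - p_occ, tolerance = 1e-12)
  expect_error(occlusion_sensitivity(m, x, patch_size = 4, stride = 0),
               "stride")
})
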