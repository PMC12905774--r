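test_that("discrimination metrics match exhaustive pair counting on small tables", {
  for (tab in make_small_tables(30)) {
    s <- tab$scores; y <- tab$cspca_label
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(average_precision(s, y), oracle_ap(s, y), tolerance = 1e-12)
    op <- threshold_at_sensitivity(s, y, 0.9)
    ref <- oracle_spec_at_sens(s, y, 0.9)
    expect_equal(op$threshold, ref$threshold)
    expect_equal(op$specificity, ref$specificity)
    expect_equal(nri(tab$probs_new, s, y), oracle_nri(tab$probs_new, s, y),
                 tolerance = 1e-12)
    expect_equal(idi(tab$probs_new, s, y), oracle_idi(tab$probs_new, s, y),
                 tolerance = 1e-12)
    expect_equal(brier(tab$probs_new, y), mean((tab$probs_new - y)^2))
    for (pt in c(0.2, 0.5))
      expect_equal(net_benefit(tab$probs_new, y, pt)$net_benefit,
                   oracle_net_benefit(tab$probs_new, y, pt), tolerance = 1e-12)
    thr <- median(s)
    expect_equal(confusion_at_threshold(s, y, thr), oracle_confusion(s, y, thr))
  }
})

test_that("AUC hits its closed-form extremes and is rank invariant", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4, 5), y), 1)
  expect_equal(roc_auc(rep(2, 5), y), 0.5)
  set.seed(1)
  s <- rnorm(50); yy <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(s, yy), roc_auc(exp(3 * s) + 2, yy))  # monotone map
  expect_error(roc_auc(s, rep(1, 50)), "both classes")
})

test_that("average precision approaches prevalence for uninformative scores", {
  expect_equal(average_precision(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  set.seed(4)
  n <- 1e5; prev <- 0.3
  y <- rbinom(n, 1, prev)
  ap <- average_precision(runif(n), y)
  expect_lt(abs(ap - prev), 0.01)
  expect_error(average_precision(runif(5), rep(0, 5)), "no events")
})

test_that("fixed-sensitivity thresholds behave on discrete and continuous scores", {
  ev <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  s <- c(ev, 0.1, 0.3, 0.5)
  y <- c(rep(1, 5), rep(0, 3))
  op <- threshold_at_sensitivity(s, y, 0.8)
  expect_equal(op$threshold, 0.4)        # 4/5 events called
  expect_equal(op$sensitivity, 0.8)
  # perfect separation: specificity 1 at the achieving threshold
  op2 <- threshold_at_sensitivity(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0), 0.9)
  expect_equal(op2$specificity, 1)
  # identically distributed classes: specificity tends to 1 - target
  set.seed(9)
  s3 <- runif(1e5); y3 <- rbinom(1e5, 1, 0.4)
  op3 <- threshold_at_sensitivity(s3, y3, 0.9)
  expect_lt(abs(op3$specificity - 0.1), 0.01)
  expect_error(threshold_at_sensitivity(s, y, 1.5), "target")
})

test_that("reclassification statistics obey their identities", {
  set.seed(2)
  p <- runif(20); y <- rep(c(0, 1), 10)
  expect_equal(nri(p, p, y), 0)
  expect_equal(idi(p, p, y), 0)
  pn <- ifelse(y == 1, p + 0.1, p - 0.1)
  expect_equal(nri(pn, p, y), 2)          # maximal improvement
  pe <- p; pe[y == 1] <- p[y == 1] + 0.1
  expect_equal(idi(pe, p, y), 0.1, tolerance = 1e-12)
})

test_that("Brier and calibration behave on certain and simulated forecasts", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 10), rep(c(0, 1), 5)), 0.25)
  set.seed(6)
  n <- 1e5
  p <- runif(n)
  y <- rbinom(n, 1, p)
  cb <- calibration_bins(p, y, n_bins = 10)
  for (b in 1:10) {
    se <- sqrt(cb$mean_predicted[b] * (1 - cb$mean_predicted[b]) / cb$n[b])
    expect_lt(abs(cb$observed_rate[b] - cb$mean_predicted[b]), 3 * se + 1e-9)
  }
  expect_error(calibration_bins(numeric(0), integer(0)), "empty")
})

test_that("net benefit reproduces the treat-none and perfect-classifier limits", {
  set.seed(3)
  y <- rbinom(40, 1, 0.4)
  nb <- net_benefit(rep(0, 40), y, c(0.1, 0.3))   # never call positive
  expect_equal(nb$net_benefit, c(0, 0))
  expect_equal(nb$treat_none, c(0, 0))
  p_perf <- ifelse(y == 1, 0.9, 0.05)
  nbp <- net_benefit(p_perf, y, c(0.1, 0.3, 0.5))
  expect_equal(nbp$net_benefit, rep(mean(y), 3))  # FP = 0 below min event prob
  expect_equal(nrow(net_benefit(p_perf, y, c(0.5, 1))), 1)  # pt = 1 excluded
})

test_that("confusion counts cover the degenerate thresholds", {
  s <- c(0.1, 0.5, 0.9); y <- c(0, 1, 1)
  lo <- confusion_at_threshold(s, y, 0)
  expect_equal(unname(lo[c("tn", "fn")]), c(0, 0))
  hi <- confusion_at_threshold(s, y, 2)
  expect_equal(unname(hi[c("tp", "fp")]), c(0, 0))
  expect_equal(sum(lo), 3)
  expect_error(confusion_at_threshold(s, y, Inf), "finite")
})

test_that("bootstrap is deterministic, null-stable and level-monotone", {
  set.seed(8)
  tab <- data.frame(cspca_label = rbinom(80, 1, 0.4), s = runif(80),
                    site_id = rep(c("a", "b"), 40))
  fn <- function(t) c(auc = roc_auc(t$s, t$cspca_label),
                      self_nri = nri(t$s, t$s, t$cspca_label))
  b1 <- bootstrap_eval(tab, fn, n_boot = 300, seed = 5)
  b2 <- bootstrap_eval(tab, fn, n_boot = 300, seed = 5)
  expect_identical(b1$ci, b2$ci)
  # a model against itself: exactly zero with a zero-width interval
  expect_identical(unname(b1$point["self_nri"]), 0)
  expect_equal(unname(b1$ci[, "self_nri"]), c(0, 0))
  # wider nominal level never shrinks the interval
  b90 <- bootstrap_eval(tab, fn, n_boot = 300, seed = 5, level = 0.90)
  expect_gte(b1$ci[2, "auc"] - b1$ci[1, "auc"],
             b90$ci[2, "auc"] - b90$ci[1, "auc"])
  # site-stratified resampling preserves per-site counts
  b_site <- bootstrap_eval(tab, function(t) c(n_a = sum(t$site_id == "a")),
                           n_boot = 20, seed = 1, clustering = "by_site")
  expect_equal(unname(b_site$ci[1, ]), 40)
  expect_equal(unname(b_site$ci[2, ]), 40)
})

test_that("delta specificity is antisymmetric between two models", {
  set.seed(12)
  y <- rbinom(60, 1, 0.5)
  a <- runif(60) + 0.5 * y
  b <- runif(60) + 0.3 * y
  spec_a <- threshold_at_sensitivity(a, y, 0.9)$specificity
  spec_b <- threshold_at_sensitivity(b, y, 0.9)$specificity
  expect_equal((spec_a - spec_b), -(spec_b - spec_a))
})

test_that("Bonferroni thresholds match exact division and printed rounding", {
  b7 <- bonferroni_alpha(0.05, 7)
  expect_equal(b7$raw, 0.05 / 7)
  expect_equal(b7$rounded, 0.007)
  expect_equal(bonferroni_alpha(0.05, 1)$raw, 0.05)
  expect_equal(bonferroni_alpha(0.05, 5)$raw, 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("heterogeneity statistics follow the stated formulas", {
  fr <- cochran_i2(c(0.6, 0.8), c(0.05, 0.05))
  expect_equal(fr$cochran_q, 8)
  expect_equal(fr$i_squared, 87.5)
  same <- cochran_i2(c(0.7, 0.7, 0.7), c(0.1, 0.2, 0.05))
  expect_equal(same$i_squared, 0)
  set.seed(14)
  for (k in 1:20) {
    est <- rnorm(5); se <- runif(5, 0.01, 1)
    i2 <- cochran_i2(est, se)$i_squared
    expect_gte(i2, 0); expect_lte(i2, 100)
  }
  expect_error(cochran_i2(c(0.5, 0.6), c(0, 0.1)), "zero")
  expect_error(cochran_i2(0.5, 0.1), "2 sites")
})

test_that("LOCO splits partition the cohort with stratified validation", {
  set.seed(20)
  manifest <- data.frame(
    patient_id = sprintf("p%03d", 1:120),
    site_id = rep(c("s1", "s2", "s3"), each = 40),
    cspca_label = rbinom(120, 1, 0.4), stringsAsFactors = FALSE)
  sp <- loco_split(manifest, "s2", 0.10, seed = 2,
                   always_train_sites = "s3")
  all_ids <- sort(c(sp$train_ids, sp$val_ids, sp$test_ids))
  expect_identical(all_ids, sort(manifest$patient_id))
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_identical(sort(sp$test_ids),
                   sort(manifest$patient_id[manifest$site_id == "s2"]))
  # stratification: validation prevalence within one patient of the pool rate
  pool <- manifest[manifest$site_id != "s2", ]
  val_lab <- manifest$cspca_label[match(sp$val_ids, manifest$patient_id)]
  expected_pos <- mean(pool$cspca_label) * length(val_lab)
  expect_lte(abs(sum(val_lab) - expected_pos), 1)
  expect_error(loco_split(manifest, "s3", always_train_sites = "s3"),
               "always-train")
  expect_error(loco_split(manifest, "nope"), "unknown site")
})
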