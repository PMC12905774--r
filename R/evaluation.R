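## Patient-level evaluation statistics: discrimination, fixed-sensitivity
## operating points, reclassification, calibration, decision curves,
## percentile bootstrap, heterogeneity, and leave-one-center-out
## orchestration.

check_two_class <- function(labels) {
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Mann-Whitney statistic with tie correction (tied score pairs count 1/2).
#'
#' @param scores Numeric risk scores (higher = more suspicious).
#' @param labels Binary labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  check_two_class(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise)
#'
#' Sum of precision times recall increment over the descending-score sweep
#' (ties handled as a single threshold step).
#'
#' @inheritParams roc_auc
#' @return AP in `(0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("no events: average precision undefined")
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ctp <- cumsum(y); cn <- seq_along(y)
  last <- !duplicated(s, fromLast = TRUE)  # last row of each tie group
  tp <- ctp[last]; n_call <- cn[last]
  prec <- tp / n_call
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Operating threshold at fixed sensitivity
#'
#' Returns the largest threshold c (positive call when `score >= c`) whose
#' sensitivity is at least `target`, plus the sensitivity and specificity at
#' that cut. Works identically for discrete (PI-RADS) and continuous
#' scores; no interpolation.
#'
#' @inheritParams roc_auc
#' @param target Required sensitivity in (0, 1].
#' @return List `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_at_sensitivity <- function(scores, labels, target = 0.90) {
  if (target <= 0 || target > 1) stop("target sensitivity must be in (0, 1]")
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0) stop("no events")
  cand <- sort(unique(scores), decreasing = TRUE)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  for (c_ in cand) {
    sens <- mean(pos >= c_)
    if (sens >= target) {
      spec <- if (length(neg) > 0) mean(neg < c_) else NA_real_
      return(list(threshold = c_, sensitivity = sens, specificity = spec))
    }
  }
  # always reachable at the minimum score (sensitivity 1)
  c_ <- min(scores)
  list(threshold = c_, sensitivity = 1,
       specificity = if (length(neg) > 0) mean(neg < c_) else NA_real_)
}

#' Continuous (category-free) net reclassification improvement
#'
#' `[P(up | event) - P(down | event)] + [P(down | nonevent) -
#' P(up | nonevent)]` where up/down are strict increases/decreases from
#' `p_old` to `p_new`; ties contribute zero. Range `[-2, 2]`.
#'
#' @param p_new,p_old Risk estimates from the new and reference model.
#' @param labels Binary labels.
#' @return NRI.
#' @export
nri <- function(p_new, p_old, labels) {
  labels <- as.integer(labels)
  check_two_class(labels)
  d <- p_new - p_old
  ev <- labels == 1
  (mean(d[ev] > 0) - mean(d[ev] < 0)) + (mean(d[!ev] < 0) - mean(d[!ev] > 0))
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes:
#' `[mean(p_new | event) - mean(p_new | nonevent)] - [mean(p_old | event) -
#' mean(p_old | nonevent)]`.
#'
#' @inheritParams nri
#' @return IDI.
#' @export
idi <- function(p_new, p_old, labels) {
  labels <- as.integer(labels)
  check_two_class(labels)
  ev <- labels == 1
  (mean(p_new[ev]) - mean(p_new[!ev])) - (mean(p_old[ev]) - mean(p_old[!ev]))
}

#' Brier score
#'
#' Mean squared error between predicted probability and binary outcome.
#'
#' @param probabilities Predicted probabilities in `[0, 1]`.
#' @param labels Binary labels.
#' @return Brier score.
#' @export
brier <- function(probabilities, labels) {
  if (length(probabilities) == 0) stop("empty input")
  mean((probabilities - as.integer(labels))^2)
}

#' Equal-width calibration bins
#'
#' @inheritParams brier
#' @param n_bins Number of equal-width bins on `[0, 1]`.
#' @return Data.frame: `bin`, `mean_predicted`, `observed_rate`, `n`.
#' @export
calibration_bins <- function(probabilities, labels, n_bins = 10) {
  if (length(probabilities) == 0) stop("empty input")
  labels <- as.integer(labels)
  bin <- pmin(pmax(ceiling(probabilities * n_bins), 1L), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    mean_predicted = NA_real_,
                    observed_rate = NA_real_,
                    n = 0L)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    out$n[b] <- sum(sel)
    if (any(sel)) {
      out$mean_predicted[b] <- mean(probabilities[sel])
      out$observed_rate[b] <- mean(labels[sel])
    }
  }
  out
}

#' Decision-curve net benefit
#'
#' `NB(pt) = TP/n - (FP/n) * pt / (1 - pt)` with a positive call when the
#' probability is at least the threshold probability `pt`; treat-all and
#' treat-none reference strategies are included. Thresholds of 1 are
#' excluded.
#'
#' @inheritParams brier
#' @param thresholds Threshold probabilities in (0, 1).
#' @return Data.frame: `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
net_benefit <- function(probabilities, labels, thresholds = seq(0.05, 0.95, by = 0.05)) {
  labels <- as.integer(labels)
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(labels)
  prev <- mean(labels)
  rows <- lapply(thresholds, function(pt) {
    call_pos <- probabilities >= pt
    tp <- sum(call_pos & labels == 1)
    fp <- sum(call_pos & labels == 0)
    w <- pt / (1 - pt)
    data.frame(threshold = pt,
               net_benefit = tp / n - (fp / n) * w,
               treat_all = prev - (1 - prev) * w,
               treat_none = 0)
  })
  do.call(rbind, rows)
}

#' Confusion counts at a threshold
#'
#' Positive call when `score >= threshold`.
#'
#' @inheritParams roc_auc
#' @param threshold Finite decision threshold.
#' @return Named vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  labels <- as.integer(labels)
  call_pos <- scores >= threshold
  c(tp = sum(call_pos & labels == 1),
    fp = sum(call_pos & labels == 0),
    tn = sum(!call_pos & labels == 0),
    fn = sum(!call_pos & labels == 1))
}

#' Percentile bootstrap of arbitrary prediction-table statistics
#'
#' Resamples patients with replacement (optionally within site strata, or
#' whole sites when `cluster_resample`), recomputes `metric_fn` inside every
#' resample (so fixed-sensitivity thresholds are re-derived per resample),
#' and returns 2.5/97.5 percentile confidence intervals, bootstrap medians,
#' and two-sided sign-based p-values (floored at `2 / n_boot`) for each
#' statistic. Resamples that lose a class are redrawn (counted, capped).
#'
#' @param table Data.frame with at least a `cspca_label` column (and
#'   `site_id` when `clustering = "by_site"`).
#' @param metric_fn Function of a resampled table returning a named numeric
#'   vector.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param clustering `"none"` (patient-level) or `"by_site"` (resampling
#'   within site strata).
#' @param cluster_resample With `by_site`, resample whole sites instead of
#'   patients within sites.
#' @param level Confidence level of the percentile interval (default 0.95).
#' @param max_redraw Cap on redraws of degenerate (single-class) resamples.
#' @return List: `point`, `boot_median`, `ci` (2 x k matrix), `p_value`,
#'   `n_boot`, `n_redrawn`, `boot` (n_boot x k matrix).
#' @export
bootstrap_eval <- function(table, metric_fn, n_boot = 10000, seed = 1L,
                           clustering = c("none", "by_site"),
                           cluster_resample = FALSE, level = 0.95,
                           max_redraw = 1000L) {
  clustering <- match.arg(clustering)
  set.seed(seed)
  point <- metric_fn(table)
  k <- length(point)
  boot <- matrix(NA_real_, n_boot, k,
                 dimnames = list(NULL, names(point)))
  n <- nrow(table)
  sites <- if (clustering == "by_site") split(seq_len(n), table$site_id) else NULL
  n_redrawn <- 0L
  draw_idx <- function() {
    if (clustering == "none") {
      sample.int(n, n, replace = TRUE)
    } else if (cluster_resample) {
      picked <- sample(names(sites), length(sites), replace = TRUE)
      unlist(sites[picked], use.names = FALSE)
    } else {
      unlist(lapply(sites, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
    }
  }
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- draw_idx()
      if (length(unique(table$cspca_label[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > max_redraw)
        stop("too many degenerate bootstrap resamples (single class)")
    }
    boot[b, ] <- metric_fn(table[idx, , drop = FALSE])
  }
  ci <- apply(boot, 2, quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  pv <- apply(boot, 2, function(v) {
    v <- v[is.finite(v)]
    max(2 * min(mean(v <= 0), mean(v >= 0)), 2 / n_boot)
  })
  list(point = point,
       boot_median = apply(boot, 2, median, na.rm = TRUE),
       ci = ci, p_value = pv, n_boot = n_boot, n_redrawn = n_redrawn,
       boot = boot)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons (>= 1).
#' @return List `raw` (`alpha / m`) and `rounded` (3 decimals).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 7) {
  if (m < 1) stop("m must be >= 1")
  raw <- alpha / m
  list(raw = raw, rounded = round(raw, 3))
}

#' Fixed-effect heterogeneity across sites (Cochran's Q and I-squared)
#'
#' Inverse-variance weights `w = 1/SE^2`; pooled estimate
#' `sum(w * est) / sum(w)`; `Q = sum(w * (est - pooled)^2)`;
#' `I2 = max(0, (Q - (k - 1)) / Q) * 100`.
#'
#' @param estimates Per-site estimates.
#' @param ses Per-site standard errors (> 0).
#' @param site_ids Optional site labels.
#' @param n Optional per-site sample sizes (carried through).
#' @return A `forest_result`: `sites` data.frame, `pooled`, `cochran_q`,
#'   `i_squared`.
#' @export
cochran_i2 <- function(estimates, ses, site_ids = NULL, n = NULL) {
  if (length(estimates) < 2) stop("need at least 2 sites")
  if (any(ses <= 0)) stop("zero or negative standard error: degenerate weight")
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  q <- sum(w * (estimates - pooled)^2)
  k <- length(estimates)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  structure(list(
    sites = data.frame(site_id = site_ids %||% paste0("site", seq_len(k)),
                       estimate = estimates, se = ses,
                       n = n %||% rep(NA_integer_, k)),
    pooled = pooled, cochran_q = q, i_squared = i2),
    class = "forest_result")
}

#' Leave-one-center-out split with stratified internal validation
#'
#' Test = every patient of the held-out site; internal validation = a
#' stratified `internal_val_fraction` of the remaining patients (matched by
#' csPCa label), used for best-epoch selection only; train = the rest.
#' Sites listed in `always_train_sites` never rotate into the test fold.
#'
#' @param manifest Cohort manifest (`patient_id`, `site_id`, `cspca_label`).
#' @param holdout_site Site to hold out.
#' @param internal_val_fraction Stratified validation fraction.
#' @param seed RNG seed for the stratified draw.
#' @param always_train_sites Sites excluded from the holdout rotation.
#' @return List `train_ids`, `val_ids`, `test_ids` (patient ids; disjoint,
#'   covering the cohort).
#' @export
loco_split <- function(manifest, holdout_site, internal_val_fraction = 0.10,
                       seed = 1L, always_train_sites = character(0)) {
  if (!holdout_site %in% manifest$site_id)
    stop("unknown site: ", holdout_site)
  if (holdout_site %in% always_train_sites)
    stop("site ", holdout_site, " is designated always-train and cannot be held out")
  set.seed(seed)
  test <- manifest$site_id == holdout_site
  rest <- which(!test)
  val_local <- stratified_split(manifest$cspca_label[rest], internal_val_fraction)
  val <- rest[val_local]
  train <- setdiff(rest, val)
  list(train_ids = manifest$patient_id[train],
       val_ids = manifest$patient_id[val],
       test_ids = manifest$patient_id[which(test)])
}

#' Per-model metric report with bootstrap confidence intervals
#'
#' Computes, for each score column, AUC, average precision, the fixed-
#' sensitivity operating point (threshold and specificity), the difference
#' in specificity versus the reference model at that operating point, NRI
#' and IDI versus the reference, and the Brier score; every statistic is
#' recomputed inside each bootstrap resample (thresholds re-derived), with
#' percentile CIs, bootstrap medians, and a two-sided bootstrap p-value for
#' the AUC difference versus the reference.
#'
#' @param table Prediction table: `cspca_label` plus one column per model.
#' @param models Score column names.
#' @param reference Reference model column (default `"model1"`, PI-RADS).
#' @param target_sens Fixed sensitivity (default 0.90).
#' @param n_boot,seed,clustering Passed to [bootstrap_eval()].
#' @param alpha,n_comparisons Bonferroni inputs recorded on the report.
#' @return A `metric_report`: `table` (per-model data.frame), `bonferroni`,
#'   `reference`, `boot` (raw bootstrap object).
#' @export
metric_report <- function(table, models, reference = "model1",
                          target_sens = 0.90, n_boot = 2000, seed = 1L,
                          clustering = "none", alpha = 0.05,
                          n_comparisons = 7) {
  stopifnot(reference %in% models)
  metric_fn <- function(tab) {
    y <- tab$cspca_label
    ref_scores <- tab[[reference]]
    ref_op <- threshold_at_sensitivity(ref_scores, y, target_sens)
    out <- c()
    for (m in models) {
      s <- tab[[m]]
      op <- threshold_at_sensitivity(s, y, target_sens)
      vals <- c(auc = roc_auc(s, y),
                ap = average_precision(s, y),
                threshold = op$threshold,
                specificity = op$specificity,
                delta_spec = op$specificity - ref_op$specificity,
                nri = nri(s, ref_scores, y),
                idi = idi(s, ref_scores, y),
                brier = brier(s, y),
                auc_diff = roc_auc(s, y) - roc_auc(ref_scores, y))
      names(vals) <- paste(m, names(vals), sep = ".")
      out <- c(out, vals)
    }
    out
  }
  bt <- bootstrap_eval(table, metric_fn, n_boot = n_boot, seed = seed,
                       clustering = clustering)
  stats <- c("auc", "ap", "threshold", "specificity", "delta_spec",
             "nri", "idi", "brier")
  rows <- lapply(models, function(m) {
    row <- data.frame(model = m, stringsAsFactors = FALSE)
    for (st in stats) {
      key <- paste(m, st, sep = ".")
      row[[paste0(st, "_point")]] <- unname(bt$point[key])
      row[[paste0(st, "_median")]] <- unname(bt$boot_median[key])
      row[[paste0(st, "_lo")]] <- unname(bt$ci[1, key])
      row[[paste0(st, "_hi")]] <- unname(bt$ci[2, key])
    }
    row$p_value_auc_vs_reference <-
      if (m == reference) NA_real_ else unname(bt$p_value[paste(m, "auc_diff", sep = ".")])
    row
  })
  structure(list(table = do.call(rbind, rows),
                 bonferroni = bonferroni_alpha(alpha, n_comparisons),
                 reference = reference, target_sens = target_sens,
                 boot = bt[c("n_boot", "n_redrawn")]),
            class = "metric_report")
}

#' Per-site forest analysis of a metric
#'
#' Bootstraps the metric within each site to obtain a site-level standard
#' error, then pools across sites with [cochran_i2()].
#'
#' @param table Prediction table with `site_id`.
#' @param score_col Model score column.
#' @param metric `"auc"` or `"spec_at_sens"`.
#' @param target_sens Fixed sensitivity for `"spec_at_sens"`.
#' @param n_boot,seed Bootstrap controls.
#' @return A `forest_result`, or `NULL` if fewer than two sites have both
#'   classes.
#' @export
forest_by_site <- function(table, score_col, metric = c("auc", "spec_at_sens"),
                           target_sens = 0.90, n_boot = 500, seed = 1L) {
  metric <- match.arg(metric)
  fn <- function(tab) {
    if (metric == "auc") c(est = roc_auc(tab[[score_col]], tab$cspca_label))
    else c(est = threshold_at_sensitivity(tab[[score_col]], tab$cspca_label,
                                          target_sens)$specificity)
  }
  sites <- split(table, table$site_id)
  keep <- vapply(sites, function(s) length(unique(s$cspca_label)) == 2, TRUE)
  sites <- sites[keep]
  if (length(sites) < 2) return(NULL)
  est <- se <- numeric(length(sites))
  for (i in seq_along(sites)) {
    bt <- bootstrap_eval(sites[[i]], fn, n_boot = n_boot, seed = seed + i)
    est[i] <- unname(bt$point)
    se[i] <- max(sd(bt$boot[, 1], na.rm = TRUE), 1e-6)
  }
  cochran_i2(est, se, site_ids = names(sites),
             n = vapply(sites, nrow, 0L))
}
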