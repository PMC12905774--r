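## Leave-one-center-out orchestration and end-to-end pipeline / reporting.

#' Run the full leave-one-center-out evaluation
#'
#' For every rotatable site: split the cohort ([loco_split()]), fit the RSI
#' biomarker for all patients, train the bpMRI and bpMRI+RSI classifiers on
#' the training fold (internal validation used for best-epoch selection
#' only), fit the logistic fusion models on the training fold, and predict
#' the held-out site. Held-out predictions are aggregated (each patient
#' predicted exactly once), restricted to the BN-BC evaluation subset, and
#' summarized with [metric_report()] (PI-RADS model as reference) and
#' per-site forest heterogeneity analyses.
#'
#' @param cohort A cohort directory (from [write_cohort()]) or an in-memory
#'   list with `studies` and `manifest`.
#' @param net_preset `"tiny"` or `"paper"` classifier preset.
#' @param crop_shape Input tensor spatial shape.
#' @param tcfg A [train_config()].
#' @param fit_cfg An [rsi_fit_config()]; defaults to the studies' b-values.
#' @param n_boot Bootstrap resamples for the metric report.
#' @param n_boot_forest Bootstrap resamples per site for forest SEs.
#' @param seed Master seed; per-fold seeds are derived from it.
#' @param target_sens Fixed sensitivity for operating points.
#' @param always_train_sites Sites never held out; `"auto"` keeps the
#'   smallest site in training whenever more than two sites exist.
#' @param clustering Bootstrap clustering mode for the report.
#' @return List: `predictions` (aggregated table), `bnbc` (evaluation
#'   subset), `report` (`metric_report`), `forest_auc`, `forest_spec`
#'   (per-model lists of `forest_result`), `fusion_specs` (per fold),
#'   `folds`.
#' @export
run_loco_evaluation <- function(cohort, net_preset = "tiny",
                                crop_shape = c(16L, 16L, 12L),
                                tcfg = train_config(total_epochs = 3L),
                                fit_cfg = NULL, n_boot = 1000, n_boot_forest = 200,
                                seed = 1L, target_sens = 0.90,
                                always_train_sites = "auto",
                                clustering = "none") {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  manifest <- cohort$manifest
  studies <- cohort$studies
  names(studies) <- vapply(studies, `[[`, "", "patient_id")
  studies <- studies[manifest$patient_id]

  # RSI biomarker and model input tensors for every patient
  tens_bp <- vector("list", nrow(manifest))
  tens_rsi <- vector("list", nrow(manifest))
  rsmax <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    st <- studies[[i]]
    fc <- fit_cfg %||% rsi_fit_config(b_values = st$b_values)
    rsi <- rsi_biomarker(st, fc)
    rsmax[i] <- rsi$rsirs_max
    tens_bp[[i]] <- assemble_input(st, NULL, "bpmri", crop_shape)
    tens_rsi[[i]] <- assemble_input(st, rsi$compartments, "bpmri_rsi",
                                    crop_shape, rsirs_max_value = rsi$rsirs_max)
  }

  site_sizes <- table(manifest$site_id)
  if (identical(always_train_sites, "auto")) {
    always_train_sites <- if (length(site_sizes) > 2)
      names(site_sizes)[which.min(site_sizes)] else character(0)
  }
  rotatable <- setdiff(names(site_sizes), always_train_sites)
  if (length(rotatable) < 2)
    stop("need at least two rotatable sites for leave-one-center-out")

  pred_rows <- list()
  fusion_specs <- list()
  folds <- list()
  for (fi in seq_along(rotatable)) {
    site <- rotatable[fi]
    fold_seed <- seed + 1000L * fi
    sp <- loco_split(manifest, site, tcfg$internal_val_fraction,
                     seed = fold_seed, always_train_sites = always_train_sites)
    fold_fit_ids <- c(sp$train_ids, sp$val_ids)   # everything except held-out
    fit_pos <- match(fold_fit_ids, manifest$patient_id)
    val_local <- match(sp$val_ids, fold_fit_ids)
    y_fit <- manifest$cspca_label[fit_pos]

    tc <- tcfg; tc$seed <- fold_seed
    cfg_bp <- densenet_config(in_channels = 3L, scalar_fusion = FALSE,
                              preset = net_preset)
    cfg_rsi <- densenet_config(in_channels = 5L, scalar_fusion = TRUE,
                               preset = net_preset)
    mdl_bp <- train_classifier(tens_bp[fit_pos], y_fit, cfg_bp, tc,
                               val_indices = val_local)
    mdl_rsi <- train_classifier(tens_rsi[fit_pos], y_fit, cfg_rsi, tc,
                                scalars = rsmax[fit_pos],
                                val_indices = val_local)

    fold_data <- data.frame(
      patient_id = manifest$patient_id,
      site_id = manifest$site_id,
      cohort_flag = manifest$cohort_flag,
      pirads = manifest$pirads,
      cspca_label = manifest$cspca_label,
      rsirs_max = rsmax,
      dl_bpmri_prob = predict_proba(mdl_bp, tens_bp),
      dl_bpmri_rsi_prob = predict_proba(mdl_rsi, tens_rsi, scalars = rsmax),
      stringsAsFactors = FALSE)
    roster <- run_model_roster(fold_data, train_idx = fit_pos,
                               test_sites = site)
    fusion_specs[[site]] <- roster$specs
    test_pos <- match(sp$test_ids, manifest$patient_id)
    pred_rows[[site]] <- cbind(fold_data[test_pos,
                                         c("patient_id", "site_id", "cohort_flag",
                                           "cspca_label", "pirads", "rsirs_max")],
                               roster$scores[test_pos, paste0("model", 1:7)])
    folds[[site]] <- list(split = sp, best_epoch_bp = mdl_bp$best_epoch,
                          best_epoch_rsi = mdl_rsi$best_epoch)
  }

  predictions <- do.call(rbind, pred_rows)
  rownames(predictions) <- NULL
  if (anyDuplicated(predictions$patient_id))
    stop("leakage check failed: a patient was predicted more than once")

  bnbc <- predictions[predictions$cohort_flag == "BN-BC", , drop = FALSE]
  models <- paste0("model", 1:7)
  report <- metric_report(bnbc, models, reference = "model1",
                          target_sens = target_sens, n_boot = n_boot,
                          seed = seed, clustering = clustering)
  forest_auc <- lapply(setNames(models, models), function(m)
    forest_by_site(bnbc, m, "auc", n_boot = n_boot_forest, seed = seed))
  forest_spec <- lapply(setNames(models, models), function(m)
    forest_by_site(bnbc, m, "spec_at_sens", target_sens = target_sens,
                   n_boot = n_boot_forest, seed = seed))
  list(predictions = predictions, bnbc = bnbc, report = report,
       forest_auc = forest_auc, forest_spec = forest_spec,
       fusion_specs = fusion_specs, folds = folds)
}

#' End-to-end pipeline configuration
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort.
#' @param crop_shape,net_preset,tcfg,n_boot,n_boot_forest,target_sens,clustering
#'   Passed to [run_loco_evaluation()].
#' @param seed Master seed for every stage.
#' @param alpha,n_comparisons Bonferroni settings.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            crop_shape = c(16L, 16L, 12L),
                            net_preset = "tiny",
                            tcfg = train_config(total_epochs = 3L),
                            n_boot = 1000, n_boot_forest = 200,
                            target_sens = 0.90, clustering = "none",
                            seed = 1L, alpha = 0.05, n_comparisons = 7) {
  structure(list(cohort = cohort, crop_shape = crop_shape,
                 net_preset = net_preset, tcfg = tcfg, n_boot = n_boot,
                 n_boot_forest = n_boot_forest, target_sens = target_sens,
                 clustering = clustering, seed = as.integer(seed),
                 alpha = alpha, n_comparisons = n_comparisons),
            class = "pipeline_config")
}

roc_points <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  data.frame(threshold = thr,
             tpr = vapply(thr, function(c_) mean(pos >= c_), 0),
             fpr = vapply(thr, function(c_) mean(neg >= c_), 0))
}

pr_points <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  rows <- lapply(thr, function(c_) {
    call_pos <- scores >= c_
    tp <- sum(call_pos & labels == 1)
    data.frame(threshold = c_, recall = tp / n_pos,
               precision = if (any(call_pos)) tp / sum(call_pos) else 1)
  })
  do.call(rbind, rows)
}

#' Render a human-readable report bundle
#'
#' Writes a seven-row performance table (AUC, threshold, specificity,
#' delta-specificity, NRI, IDI with 95% CIs), per-model ROC, precision-
#' recall, decision and calibration curve tables, and two forest tables
#' (AUC and specificity at fixed sensitivity) with I-squared annotations.
#'
#' @param result Output of [run_loco_evaluation()].
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  rep_tab <- result$report$table
  fmt <- function(p, lo, hi) sprintf("%.3f (%.3f to %.3f)", p, lo, hi)
  pretty <- data.frame(
    model = rep_tab$model,
    auc = fmt(rep_tab$auc_median, rep_tab$auc_lo, rep_tab$auc_hi),
    threshold = fmt(rep_tab$threshold_median, rep_tab$threshold_lo, rep_tab$threshold_hi),
    specificity = fmt(rep_tab$specificity_median, rep_tab$specificity_lo,
                      rep_tab$specificity_hi),
    delta_specificity = fmt(rep_tab$delta_spec_median, rep_tab$delta_spec_lo,
                            rep_tab$delta_spec_hi),
    nri = fmt(rep_tab$nri_median, rep_tab$nri_lo, rep_tab$nri_hi),
    idi = fmt(rep_tab$idi_median, rep_tab$idi_lo, rep_tab$idi_hi),
    stringsAsFactors = FALSE)
  p <- file.path(out_dir, "performance_table.csv")
  write.csv(pretty, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(out_dir, "performance_table_raw.csv")
  write.csv(rep_tab, p, row.names = FALSE); paths <- c(paths, p)

  bnbc <- result$bnbc
  models <- paste0("model", 1:7)
  curves <- list(roc = list(), pr = list(), decision = list(), calibration = list())
  for (m in models) {
    s <- bnbc[[m]]; y <- bnbc$cspca_label
    curves$roc[[m]] <- cbind(model = m, roc_points(s, y))
    curves$pr[[m]] <- cbind(model = m, pr_points(s, y))
    curves$decision[[m]] <- cbind(model = m, net_benefit(s, y))
    curves$calibration[[m]] <- cbind(model = m, calibration_bins(s, y))
  }
  for (nm in names(curves)) {
    p <- file.path(out_dir, paste0(nm, "_curves.csv"))
    write.csv(do.call(rbind, curves[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }

  forest_table <- function(fl) {
    rows <- lapply(names(fl), function(m) {
      fr <- fl[[m]]
      if (is.null(fr)) return(NULL)
      cbind(model = m, fr$sites, pooled = fr$pooled,
            cochran_q = fr$cochran_q, i_squared = fr$i_squared)
    })
    do.call(rbind, rows)
  }
  for (nm in c("forest_auc", "forest_spec")) {
    ft <- forest_table(result[[nm]])
    if (!is.null(ft)) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write.csv(ft, p, row.names = FALSE); paths <- c(paths, p)
    }
  }
  p <- file.path(out_dir, "predictions.csv")
  write.csv(result$predictions, p, row.names = FALSE); paths <- c(paths, p)
  invisible(paths)
}

#' Run the whole pipeline: simulate, fit, train, evaluate, report
#'
#' Chains cohort simulation, cohort writing, the RSI biomarker fit, both
#' classifier trainings per LOCO fold, logistic fusion, evaluation, and
#' report rendering into a run directory. Every artifact is reproducible
#' from the configuration and its seeds; a JSON run manifest recording
#' parameters, seeds and input hashes is written alongside the outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory.
#' @param keep_cohort Also write the simulated NIfTI cohort under
#'   `out_dir/cohort`.
#' @return The [run_loco_evaluation()] result, invisibly.
#' @export
run_pipeline <- function(config, out_dir, keep_cohort = TRUE) {
  stage <- "simulate"
  result <- tryCatch({
    sim <- simulate_cohort(config$cohort, seed = config$seed)
    if (keep_cohort) {
      stage <- "write-cohort"
      write_cohort(sim$studies, sim$manifest, file.path(out_dir, "cohort"))
    }
    stage <- "evaluate"
    res <- run_loco_evaluation(
      sim, net_preset = config$net_preset, crop_shape = config$crop_shape,
      tcfg = config$tcfg, n_boot = config$n_boot,
      n_boot_forest = config$n_boot_forest, seed = config$seed,
      target_sens = config$target_sens, clustering = config$clustering)
    stage <- "report"
    render_report(res, file.path(out_dir, "report"))
    manifest_path <- file.path(out_dir, "cohort", "manifest.csv")
    run_info <- list(
      seed = config$seed, net_preset = config$net_preset,
      crop_shape = config$crop_shape, n_boot = config$n_boot,
      target_sens = config$target_sens,
      bonferroni = bonferroni_alpha(config$alpha, config$n_comparisons),
      n_patients = nrow(sim$manifest),
      n_bnbc = sum(sim$manifest$cohort_flag == "BN-BC"),
      manifest_md5 = if (file.exists(manifest_path))
        unname(tools::md5sum(manifest_path)) else NULL)
    jsonlite::write_json(run_info, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
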