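## Logistic-regression fusion of PI-RADS, RSIrs_max and classifier output
## probabilities: the seven-model roster.

#' Feature sets of the seven-model roster
#'
#' Model 1 = PI-RADS; 2 = RSIrs_max; 3 = bpMRI CNN probability;
#' 4 = bpMRI+RSI CNN probability; 5 = PI-RADS + RSIrs_max;
#' 6 = PI-RADS + bpMRI CNN probability;
#' 7 = PI-RADS + bpMRI+RSI CNN probability. Models 1, 2, 5, 6, 7 are
#' logistic regressions; 3 and 4 are the raw CNN probabilities.
#'
#' @return Named list mapping `model1`..`model7` to feature-name vectors.
#' @export
model_roster <- function() {
  list(model1 = "pirads",
       model2 = "rsirs_max",
       model3 = "dl_bpmri_prob",
       model4 = "dl_bpmri_rsi_prob",
       model5 = c("pirads", "rsirs_max"),
       model6 = c("pirads", "dl_bpmri_prob"),
       model7 = c("pirads", "dl_bpmri_rsi_prob"))
}

## ridge-penalized logistic fit by IRLS (used only as the documented
## fallback under perfect separation)
ridge_logistic <- function(X, y, lambda = 1e-3, max_iter = 100) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X1 * w, X1) + pen
    new_beta <- solve(H, crossprod(X1 * w, z))
    if (max(abs(new_beta - beta)) < 1e-10) { beta <- new_beta; break }
    beta <- new_beta
  }
  list(beta = as.vector(beta), cov = solve(H))
}

#' Fit a logistic fusion model
#'
#' Unpenalized maximum-likelihood logistic regression of the csPCa label on
#' the listed features (PI-RADS entered as a numeric 1-5 covariate), with
#' Wald 95% confidence intervals per coefficient. Under (near-)perfect
#' separation the fit falls back to a weakly ridge-penalized IRLS solve and
#' the returned spec is flagged.
#'
#' @param features Data.frame containing the feature columns.
#' @param labels Binary labels (both classes required).
#' @param feature_list Character vector of feature column names.
#' @param model_id Optional roster id (1-7) recorded on the spec.
#' @return A `fusion_spec`: `feature_list`, `coefficients` (intercept
#'   first), `ci` (matrix), `separation_fallback`, `converged`, `model_id`.
#' @export
fit_logistic <- function(features, labels, feature_list, model_id = NA_integer_) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  miss <- setdiff(feature_list, names(features))
  if (length(miss) > 0)
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(features[, feature_list, drop = FALSE])
  if (anyNA(X)) stop("missing values in features")
  df <- data.frame(X)
  names(df) <- feature_list
  df$.y <- labels
  form <- stats::as.formula(paste(".y ~", paste(feature_list, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  beta <- stats::coef(fit)
  dropped <- is.na(beta)          # aliased (e.g. constant) features carry no signal
  beta[dropped] <- 0
  separated <- !fit$converged || any(abs(beta[-1]) > 15)
  if (separated) {
    rf <- ridge_logistic(X, labels)
    beta <- rf$beta
    se <- sqrt(diag(rf$cov))
  } else {
    se <- sqrt(diag(stats::vcov(fit, complete = TRUE)))
    se[dropped] <- NA_real_
  }
  ci <- cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se)
  rownames(ci) <- c("(Intercept)", feature_list)
  structure(list(feature_list = feature_list,
                 coefficients = setNames(as.vector(beta),
                                         c("(Intercept)", feature_list)),
                 ci = ci,
                 separation_fallback = separated,
                 converged = if (separated) TRUE else fit$converged,
                 model_id = model_id),
            class = "fusion_spec")
}

#' Predict fused csPCa probabilities
#'
#' `sigmoid(intercept + sum(beta * x))` per row; probabilities are clipped
#' away from exactly 0 and 1.
#'
#' @param spec A `fusion_spec`.
#' @param features Data.frame with the spec's feature columns.
#' @param clip Probability clip bound.
#' @return Numeric probability vector.
#' @export
predict_fused <- function(spec, features, clip = 1e-12) {
  miss <- setdiff(spec$feature_list, names(features))
  if (length(miss) > 0)
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(features[, spec$feature_list, drop = FALSE])
  eta <- spec$coefficients[1] + as.vector(X %*% spec$coefficients[-1])
  pmin(pmax(1 / (1 + exp(-eta)), clip), 1 - clip)
}

#' Score every patient under the seven-model roster
#'
#' Univariable logistic scores for models 1-2, raw CNN probabilities for
#' models 3-4, and fusion logistic fits for models 5-7. All logistic models
#' are fit only on `train_idx` rows; fitting on any patient from
#' `test_sites` raises a leakage error.
#'
#' @param data Data.frame with columns `patient_id`, `site_id`, `pirads`,
#'   `rsirs_max`, `dl_bpmri_prob`, `dl_bpmri_rsi_prob`, `cspca_label`.
#' @param train_idx Row indices used to fit the logistic models.
#' @param test_sites Site ids of the current held-out center(s); rows from
#'   these sites must not appear in `train_idx`.
#' @return List with `scores` (data.frame `patient_id` + `model1`..`model7`)
#'   and `specs` (fitted `fusion_spec`s).
#' @export
run_model_roster <- function(data, train_idx = seq_len(nrow(data)),
                             test_sites = character(0)) {
  needed <- c("patient_id", "site_id", "pirads", "rsirs_max",
              "dl_bpmri_prob", "dl_bpmri_rsi_prob", "cspca_label")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(data$site_id[train_idx] %in% test_sites))
    stop("leakage: training rows include patients from held-out site(s) ",
         paste(intersect(data$site_id[train_idx], test_sites), collapse = ", "))
  roster <- model_roster()
  scores <- data.frame(patient_id = data$patient_id,
                       stringsAsFactors = FALSE)
  specs <- list()
  for (mid in names(roster)) {
    feats <- roster[[mid]]
    if (mid == "model3") {
      scores[[mid]] <- data$dl_bpmri_prob
    } else if (mid == "model4") {
      scores[[mid]] <- data$dl_bpmri_rsi_prob
    } else {
      spec <- fit_logistic(data[train_idx, , drop = FALSE],
                           data$cspca_label[train_idx], feats,
                           model_id = as.integer(sub("model", "", mid)))
      specs[[mid]] <- spec
      scores[[mid]] <- predict_fused(spec, data)
    }
  }
  list(scores = scores, specs = specs)
}
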