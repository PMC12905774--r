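#' Configuration for the four-compartment RSI fit
#'
#' Restriction spectrum imaging (RSI) models the multi-b-value DWI signal at
#' each voxel as a linear combination of exponential decays over four tissue
#' compartments — restricted intracellular water (C1), hindered
#' extracellular water (C2), free water (C3), and vascular flow (C4) — with
#' fixed, acquisition-independent diffusion coefficients.
#'
#' @param b_values Ascending nonnegative b-values, s/mm^2; at least as many
#'   as compartments for a determined fit.
#' @param compartment_adcs Four strictly increasing positive diffusion
#'   coefficients, mm^2/s (defaults as in [cohort_config()]; externally
#'   sourced, overridable).
#' @param nonnegative Constrain compartment coefficients to be nonnegative
#'   (default TRUE; signal fractions are physical quantities). Plain least
#'   squares is available for diagnostics.
#' @param rsirs_scale Multiplier applied to the restriction score map
#'   (default 1; published clinical thresholds imply a site-calibrated scale
#'   convention, which is deliberately exposed rather than guessed).
#' @return An `rsi_fit_config` object.
#' @export
rsi_fit_config <- function(b_values = c(0, 200, 1000, 2000, 3000),
                           compartment_adcs = c(1.0e-4, 1.8e-3, 3.6e-3, 1.0e-2),
                           nonnegative = TRUE,
                           rsirs_scale = 1.0) {
  if (length(b_values) < length(compartment_adcs))
    stop("need at least ", length(compartment_adcs),
         " b-values for a determined fit")
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly ascending")
  if (any(b_values < 0)) stop("b_values must be nonnegative")
  if (length(compartment_adcs) != 4 || any(compartment_adcs <= 0) ||
      any(diff(compartment_adcs) <= 0))
    stop("compartment_adcs must be 4 strictly increasing positive values")
  if (rsirs_scale <= 0) stop("rsirs_scale must be positive")
  structure(list(b_values = as.numeric(b_values),
                 compartment_adcs = as.numeric(compartment_adcs),
                 nonnegative = isTRUE(nonnegative),
                 rsirs_scale = rsirs_scale),
            class = "rsi_fit_config")
}

#' Exponential-decay design matrix of the RSI model
#'
#' Entry (j, i) is `exp(-b_j * D_i)`: the signal retained by compartment i
#' at b-value j.
#'
#' @param b_values Ascending nonnegative b-values, s/mm^2.
#' @param compartment_adcs Strictly increasing positive diffusion
#'   coefficients, mm^2/s.
#' @return Matrix of dimension `length(b_values) x length(compartment_adcs)`.
#' @export
build_design_matrix <- function(b_values, compartment_adcs) {
  if (any(diff(b_values) <= 0)) stop("b_values must be strictly ascending")
  if (any(diff(compartment_adcs) <= 0))
    stop("compartment_adcs must be strictly ascending")
  exp(-outer(as.numeric(b_values), as.numeric(compartment_adcs)))
}

## Exact NNLS for a small fixed design, vectorized over many right-hand
## sides: solve min ||A c - s||^2 s.t. c >= 0 by enumerating all support
## subsets of the 4 columns and keeping the feasible solution with the
## smallest residual (global optimum of the convex problem).
nnls_batch <- function(A, S) {
  p <- ncol(A)
  n <- nrow(S)
  C <- matrix(0, n, p)
  # unconstrained solve first; most voxels are interior
  AtA <- crossprod(A)
  coef_full <- t(solve(AtA, crossprod(A, t(S))))
  ok <- rowSums(coef_full < -1e-12) == 0
  C[ok, ] <- pmax(coef_full[ok, , drop = FALSE], 0)
  bad <- which(!ok)
  if (length(bad) > 0) {
    Sb <- S[bad, , drop = FALSE]
    best_rss <- rowSums(Sb^2)           # empty support: c = 0
    best_C <- matrix(0, length(bad), p)
    subsets <- lapply(seq_len(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
    for (sub in subsets) {
      As <- A[, sub, drop = FALSE]
      cs <- t(solve(crossprod(As), crossprod(As, t(Sb))))  # nbad x |sub|
      feas <- rowSums(cs < -1e-10) == 0
      if (!any(feas)) next
      fit <- cs %*% t(As)
      rss <- rowSums((Sb - fit)^2)
      upd <- feas & (rss < best_rss - 1e-12)
      if (any(upd)) {
        best_rss[upd] <- rss[upd]
        best_C[upd, ] <- 0
        best_C[upd, sub] <- pmax(cs[upd, , drop = FALSE], 0)
      }
    }
    C[bad, ] <- best_C
  }
  C
}

#' Fit the four-compartment RSI model at every voxel
#'
#' Per-voxel least squares of the DWI signal against the exponential-decay
#' design matrix, nonnegatively constrained by default. The constrained
#' solve enumerates active sets over the four compartments in a single
#' vectorized pass, which is exact for this small design.
#'
#' @param dwi 4-D array (x, y, z, b) of DWI magnitudes, one volume per
#'   b-value.
#' @param config An [rsi_fit_config()].
#' @param mask Optional logical volume; voxels outside are set to zero and
#'   not fitted.
#' @return A `compartment_maps` list: volumes `c1`..`c4` of signal
#'   coefficients and `residual_rms`.
#' @export
fit_compartments <- function(dwi, config, mask = NULL) {
  if (length(dim(dwi)) != 4) stop("dwi must be a 4-D array (x, y, z, b)")
  nb <- dim(dwi)[4]
  if (nb != length(config$b_values))
    stop("dwi has ", nb, " volumes but config lists ",
         length(config$b_values), " b-values")
  A <- build_design_matrix(config$b_values, config$compartment_adcs)
  if (qr(A)$rank < ncol(A))
    stop("rank-deficient design matrix: b-values/ADCs do not identify 4 compartments")
  dm <- dim(dwi)[1:3]
  nvox <- prod(dm)
  S <- matrix(dwi, nrow = nvox, ncol = nb)
  idx <- if (is.null(mask)) seq_len(nvox) else which(as.logical(mask))
  if (length(idx) == 0) stop("mask selects no voxels")
  Sm <- S[idx, , drop = FALSE]
  if (config$nonnegative) {
    Cm <- nnls_batch(A, Sm)
  } else {
    Cm <- t(solve(crossprod(A), crossprod(A, t(Sm))))
  }
  resid <- Sm - Cm %*% t(A)
  rms <- sqrt(rowMeans(resid^2))
  out <- lapply(1:4, function(i) {
    v <- numeric(nvox); v[idx] <- Cm[, i]; array(v, dim = dm)
  })
  rr <- numeric(nvox); rr[idx] <- rms
  structure(list(c1 = out[[1]], c2 = out[[2]], c3 = out[[3]], c4 = out[[4]],
                 residual_rms = array(rr, dim = dm)),
            class = "compartment_maps")
}

#' Restriction score map: C1 signal normalized by intra-prostatic T2W median
#'
#' `rsirs(v) = rsirs_scale * c1(v) / median(T2W over mask voxels)`. The map
#' is defined everywhere but interpreted within the prostate mask.
#'
#' @param c1_map Restricted-compartment coefficient volume.
#' @param t2w T2-weighted volume on the same grid.
#' @param mask Nonempty logical prostate mask.
#' @param rsirs_scale Positive multiplier (see [rsi_fit_config()]).
#' @return List with `rsirs_map`, `t2w_median_in_mask`.
#' @export
compute_rsirs <- function(c1_map, t2w, mask, rsirs_scale = 1.0) {
  if (!any(mask)) stop("empty prostate mask")
  med <- median(t2w[as.logical(mask)])
  if (!is.finite(med) || med <= 0)
    stop("nonpositive or undefined T2W median within mask")
  list(rsirs_map = rsirs_scale * c1_map / med, t2w_median_in_mask = med)
}

#' Patient-level biomarker: maximum restriction score within the prostate
#'
#' @param rsirs_map Restriction score volume.
#' @param mask Nonempty logical prostate mask.
#' @return Scalar maximum of the map over mask voxels.
#' @export
rsirs_max <- function(rsirs_map, mask) {
  if (!any(mask)) stop("empty prostate mask")
  max(rsirs_map[as.logical(mask)])
}

#' Full RSI biomarker computation for one imaging study
#'
#' Fits the compartment model, forms the restriction score map, and reduces
#' it to the patient-level maximum.
#'
#' @param study An `imaging_study`.
#' @param config An [rsi_fit_config()]; defaults to the study's b-values.
#' @return An `rsi_result` list: `compartments`, `rsirs_map`, `rsirs_max`,
#'   `t2w_median_in_mask`.
#' @export
rsi_biomarker <- function(study, config = NULL) {
  if (is.null(config))
    config <- rsi_fit_config(b_values = study$b_values)
  maps <- fit_compartments(study$dwi, config, mask = NULL)
  rs <- compute_rsirs(maps$c1, study$t2w, study$mask, config$rsirs_scale)
  structure(list(compartments = maps,
                 rsirs_map = rs$rsirs_map,
                 rsirs_max = rsirs_max(rs$rsirs_map, study$mask),
                 t2w_median_in_mask = rs$t2w_median_in_mask),
            class = "rsi_result")
}
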