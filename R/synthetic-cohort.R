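#' @importFrom stats rnorm runif rbinom median sd quantile setNames
#' @importFrom utils read.csv write.csv
NULL

#' Reference multi-center cohort characteristics
#'
#' Per-center summary counts for a seven-center prostate MRI cohort used as
#' the default template for the synthetic cohort generator: number of imaged
#' patients, number with clinically significant prostate cancer (csPCa,
#' grade group >= 2), and number who were biopsy-naive at MRI with
#' subsequent biopsy confirmation (BN-BC, the evaluation subset).
#'
#' @return A data.frame with columns `site_id`, `n_cases`, `n_cspca`,
#'   `n_bnbc`.
#' @export
reference_cohort_characteristics <- function() {
  data.frame(
    site_id = paste0("site", 1:7),
    n_cases = c(692L, 647L, 63L, 251L, 42L, 146L, 5L),
    n_cspca = c(252L, 269L, 27L, 107L, 25L, 40L, 1L),
    n_bnbc  = c(309L, 259L, 38L, 233L, 20L, 17L, 0L),
    stringsAsFactors = FALSE
  )
}

#' Default PI-RADS score distributions conditional on csPCa status
#'
#' The generator draws the ordinal radiologist PI-RADS score (1-5) from one
#' of two conditional distributions depending on the patient's csPCa label.
#' The defaults are chosen so that the implied marginal distribution at 39%
#' prevalence matches the marginal PI-RADS distribution of the reference
#' cohort (roughly 35/3/14/25/24% for scores 1-5).
#'
#' @return A list with elements `cspca` and `benign`, each a probability
#'   vector of length 5.
#' @export
default_pirads_conditionals <- function() {
  list(
    cspca  = c(0.05, 0.03, 0.10, 0.37, 0.45),
    benign = c(0.54, 0.03, 0.17, 0.17, 0.09)
  )
}

#' Describe one imaging center for the synthetic cohort generator
#'
#' @param site_id Character site label.
#' @param n_patients Number of patients to simulate at this site.
#' @param prevalence csPCa prevalence in `[0, 1]`.
#' @param bnbc_fraction Fraction of patients flagged BN-BC (biopsy-naive at
#'   MRI, biopsy-confirmed afterwards) in `[0, 1]`.
#' @param pirads_given_cspca,pirads_given_benign Length-5 probability vectors
#'   `P(PI-RADS = k | label)`; each must sum to 1 within 1e-9.
#' @param noise_sigma Rician noise scale applied to synthetic magnitude
#'   images, in signal units.
#' @return A `site_profile` object (list).
#' @export
site_profile <- function(site_id, n_patients, prevalence, bnbc_fraction,
                         pirads_given_cspca = default_pirads_conditionals()$cspca,
                         pirads_given_benign = default_pirads_conditionals()$benign,
                         noise_sigma = 2) {
  prof <- structure(
    list(site_id = as.character(site_id),
         n_patients = as.integer(n_patients),
         prevalence = prevalence,
         bnbc_fraction = bnbc_fraction,
         pirads_given_cspca = pirads_given_cspca,
         pirads_given_benign = pirads_given_benign,
         noise_sigma = noise_sigma),
    class = "site_profile")
  validate_site_profile(prof)
  prof
}

validate_site_profile <- function(prof) {
  id <- prof$site_id
  if (prof$n_patients < 1)
    stop("site '", id, "': n_patients must be positive")
  if (prof$prevalence < 0 || prof$prevalence > 1)
    stop("site '", id, "': prevalence must be in [0, 1]")
  if (prof$bnbc_fraction < 0 || prof$bnbc_fraction > 1)
    stop("site '", id, "': bnbc_fraction must be in [0, 1]")
  for (nm in c("pirads_given_cspca", "pirads_given_benign")) {
    p <- prof[[nm]]
    if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("site '", id, "': ", nm,
           " must be a length-5 probability vector summing to 1")
  }
  if (prof$noise_sigma < 0)
    stop("site '", id, "': noise_sigma must be nonnegative")
  invisible(prof)
}

#' Default site profiles mirroring the reference cohort
#'
#' One profile per reference center with the center's prevalence and BN-BC
#' fraction; `scale` shrinks every site's patient count for desk-scale runs
#' (counts are rounded up so no site is empty).
#'
#' @param scale Multiplier on per-site patient counts (default 1).
#' @param noise_sigma Rician noise scale shared by all sites.
#' @return List of [site_profile()] objects.
#' @export
default_site_profiles <- function(scale = 1, noise_sigma = 2) {
  ref <- reference_cohort_characteristics()
  lapply(seq_len(nrow(ref)), function(i) {
    site_profile(
      site_id = ref$site_id[i],
      n_patients = max(1L, as.integer(ceiling(ref$n_cases[i] * scale))),
      prevalence = ref$n_cspca[i] / ref$n_cases[i],
      bnbc_fraction = ref$n_bnbc[i] / ref$n_cases[i],
      noise_sigma = noise_sigma)
  })
}

#' Configuration for the synthetic multi-center cohort generator
#'
#' The forward model draws, for every patient, a prostate mask (centered
#' ellipsoid), per-voxel compartment signal fractions (four compartments:
#' restricted, hindered, free, vascular), focal spherical lesions with an
#' elevated restricted fraction in csPCa-positive patients, multi-b-value
#' DWI signal \eqn{S(v,b) = S_0(v) \sum_i C_i(v) e^{-b D_i}} with Rician
#' noise, and a smooth T2-weighted volume.
#'
#' @param sites List of [site_profile()] objects.
#' @param b_values Ascending nonnegative b-values, s/mm^2. At least four
#'   (including b = 0) are needed for an identifiable four-compartment fit.
#' @param compartment_adcs Four strictly increasing positive diffusion
#'   coefficients D1 < D2 < D3 < D4, mm^2/s. The defaults (1.0e-4, 1.8e-3,
#'   3.6e-3, 1.0e-2) are externally sourced from the prostate RSI
#'   literature, not estimated here; override to match an acquisition.
#' @param grid_shape Integer volume dimensions (x, y, z).
#' @param voxel_spacing Voxel size in mm per axis.
#' @param lesion_radius_range Lesion radius range (min, max) in mm.
#' @param lesion_c1_contrast Multiplier applied to the restricted-compartment
#'   fraction inside lesions before renormalization (> 1 makes lesions
#'   visible to the restriction score).
#' @param background_fractions Four nonnegative background compartment
#'   fractions summing to 1.
#' @param seed Integer seed for the whole cohort.
#' @return A `cohort_config` object (list).
#' @export
cohort_config <- function(sites = default_site_profiles(),
                          b_values = c(0, 200, 1000, 2000, 3000),
                          compartment_adcs = c(1.0e-4, 1.8e-3, 3.6e-3, 1.0e-2),
                          grid_shape = c(32L, 32L, 24L),
                          voxel_spacing = c(1, 1, 3),
                          lesion_radius_range = c(3, 6),
                          lesion_c1_contrast = 6,
                          background_fractions = c(0.05, 0.35, 0.45, 0.15),
                          seed = 1L) {
  cfg <- structure(
    list(sites = sites, b_values = as.numeric(b_values),
         compartment_adcs = as.numeric(compartment_adcs),
         grid_shape = as.integer(grid_shape),
         voxel_spacing = as.numeric(voxel_spacing),
         lesion_radius_range = as.numeric(lesion_radius_range),
         lesion_c1_contrast = lesion_c1_contrast,
         background_fractions = as.numeric(background_fractions),
         seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  for (s in cfg$sites) validate_site_profile(s)
  b <- cfg$b_values
  if (length(b) < 3 || any(diff(b) <= 0) || any(b < 0) || b[1] != 0)
    stop("b_values must be >= 3 ascending nonnegative values including b = 0")
  D <- cfg$compartment_adcs
  if (length(D) != 4 || any(D <= 0) || any(diff(D) <= 0))
    stop("compartment_adcs must be 4 strictly increasing positive values")
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 4))
    stop("grid_shape must be 3 integers >= 4")
  if (length(cfg$voxel_spacing) != 3 || any(cfg$voxel_spacing <= 0))
    stop("voxel_spacing must be 3 positive values")
  r <- cfg$lesion_radius_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1])
    stop("lesion_radius_range must be (min, max) with 0 < min <= max")
  if (cfg$lesion_c1_contrast <= 0) stop("lesion_c1_contrast must be positive")
  f <- cfg$background_fractions
  if (length(f) != 4 || any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("background_fractions must be 4 nonnegative values summing to 1")
  invisible(cfg)
}

#' Draw the clinical layer of a synthetic cohort
#'
#' Draws, per site, the csPCa labels (Bernoulli at the site prevalence),
#' cohort flags (BN-BC vs PBI-NC), and PI-RADS scores from the
#' label-conditional distributions, and assigns each patient a private
#' simulation seed so imaging synthesis is reproducible per patient.
#'
#' @param config A [cohort_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with `truths` (list of per-patient ground-truth records)
#'   and `manifest` (data.frame with columns `patient_id`, `site_id`,
#'   `cohort_flag`, `pirads`, `cspca_label`).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  set.seed(seed)
  truths <- list()
  rows <- list()
  k <- 0L
  for (prof in config$sites) {
    for (j in seq_len(prof$n_patients)) {
      k <- k + 1L
      pid <- sprintf("%s_p%03d", prof$site_id, j)
      label <- rbinom(1, 1, prof$prevalence)
      flag <- if (rbinom(1, 1, prof$bnbc_fraction) == 1) "BN-BC" else "PBI-NC"
      pcond <- if (label == 1) prof$pirads_given_cspca else prof$pirads_given_benign
      pirads <- sample.int(5L, 1L, prob = pcond)
      truths[[k]] <- structure(
        list(patient_id = pid, site_id = prof$site_id,
             cspca_label = label, cohort_flag = flag, pirads = pirads,
             noise_sigma = prof$noise_sigma,
             sim_seed = sample.int(.Machine$integer.max - 1L, 1L),
             lesion_centers = NULL, true_compartment_maps = NULL),
        class = "ground_truth")
      rows[[k]] <- data.frame(patient_id = pid, site_id = prof$site_id,
                              cohort_flag = flag, pirads = pirads,
                              cspca_label = label, stringsAsFactors = FALSE)
    }
  }
  list(truths = truths, manifest = do.call(rbind, rows))
}

## voxel center coordinates (mm) along each axis, 0-based indices
axis_coords <- function(config) {
  lapply(1:3, function(a)
    (seq_len(config$grid_shape[a]) - 1) * config$voxel_spacing[a])
}

#' Centered ellipsoid prostate mask on the configured grid
#' @keywords internal
ellipsoid_mask <- function(config, semi_frac = 0.38) {
  dm <- config$grid_shape
  co <- axis_coords(config)
  ctr <- vapply(co, function(x) mean(range(x)), 0)
  semi <- vapply(1:3, function(a) semi_frac * diff(range(co[[a]])) + 1e-9, 0)
  dx <- (co[[1]] - ctr[1]) / semi[1]
  dy <- (co[[2]] - ctr[2]) / semi[2]
  dz <- (co[[3]] - ctr[3]) / semi[3]
  q <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  array(q <= 1, dim = dm)
}

## smooth random field in [-1, 1]-ish range: trilinearly upsampled coarse noise
smooth_field <- function(dm, coarse = 4L) {
  g <- pmax(2L, pmin(dm, coarse))
  coarse_arr <- array(rnorm(prod(g)), dim = g)
  # map each fine voxel to fractional coarse coordinates and interpolate
  pos <- lapply(1:3, function(a) {
    if (dm[a] == 1) rep(1, 1) else seq(1, g[a], length.out = dm[a])
  })
  trilinear_sample_grid(coarse_arr, pos[[1]], pos[[2]], pos[[3]])
}

## trilinear interpolation of arr at the tensor grid px x py x pz
## (fractional 1-based coordinates); returns array length(px) x length(py) x length(pz)
trilinear_sample_grid <- function(arr, px, py, pz) {
  d <- dim(arr)
  f <- function(p, n) {
    i0 <- pmin(pmax(floor(p), 1), max(n - 1, 1))
    list(i0 = i0, w = p - i0)
  }
  X <- f(px, d[1]); Y <- f(py, d[2]); Z <- f(pz, d[3])
  out <- array(0, dim = c(length(px), length(py), length(pz)))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- pmin(X$i0 + dx, d[1]); iy <- pmin(Y$i0 + dy, d[2]); iz <- pmin(Z$i0 + dz, d[3])
    wx <- if (dx == 0) 1 - X$w else X$w
    wy <- if (dy == 0) 1 - Y$w else Y$w
    wz <- if (dz == 0) 1 - Z$w else Z$w
    w <- outer(outer(wx, wy, `*`), wz, `*`)
    out <- out + w * arr[ix, iy, iz, drop = FALSE][seq_along(ix),
                                                   seq_along(iy),
                                                   seq_along(iz), drop = FALSE]
  }
  out
}

#' Rician corruption of a magnitude image
#'
#' Standard magnitude-MRI noise model: `sqrt((S + n1)^2 + n2^2)` with
#' `n1, n2 ~ Normal(0, sigma)`.
#' @keywords internal
rician_noise <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n1 <- array(rnorm(length(signal), sd = sigma), dim = dim(signal))
  n2 <- array(rnorm(length(signal), sd = sigma), dim = dim(signal))
  sqrt((signal + n1)^2 + n2^2)
}

#' NIfTI affine for the configured grid (diagonal, voxel spacing on the
#' diagonal, 0-based voxel indices map to mm world coordinates)
#' @keywords internal
config_affine <- function(config) {
  A <- diag(c(config$voxel_spacing, 1))
  A
}

#' Synthesize one patient's imaging study from its ground-truth record
#'
#' Builds the centered-ellipsoid prostate mask, the per-voxel compartment
#' fraction maps (background fractions with a small smooth perturbation,
#' renormalized; csPCa-positive patients receive at least one spherical
#' lesion inside the mask where the restricted fraction is multiplied by
#' `lesion_c1_contrast` and fractions renormalized), the noiseless DWI stack
#' from the four-compartment exponential forward model, Rician noise, and a
#' smooth positive T2-weighted volume.
#'
#' @param truth A ground-truth record from [generate_cohort()].
#' @param config The [cohort_config()] the record was drawn under.
#' @param max_attempts Placement retries before shrinking the lesion radius.
#' @return An `imaging_study` list: `patient_id`, `t2w`, `dwi` (4-D array,
#'   last axis indexes b-values), `b_values`, `mask`, `affine`, `truth`
#'   (input record completed with `lesion_centers` and
#'   `true_compartment_maps`).
#' @export
synthesize_patient_volumes <- function(truth, config, max_attempts = 25L) {
  set.seed(truth$sim_seed)
  dm <- config$grid_shape
  mask <- ellipsoid_mask(config)
  co <- axis_coords(config)

  # compartment fractions: background + mild smooth spatial variation
  fr <- lapply(config$background_fractions, function(f0)
    pmax(f0 * (1 + 0.1 * smooth_field(dm)), 0))
  tot <- Reduce(`+`, fr)
  fr <- lapply(fr, function(f) f / tot)

  lesion_centers <- NULL
  if (truth$cspca_label == 1) {
    n_lesions <- 1L + rbinom(1, 1, 0.3)
    lesion_centers <- vector("list", n_lesions)
    grid_x <- co[[1]]; grid_y <- co[[2]]; grid_z <- co[[3]]
    ctr <- vapply(co, function(x) mean(range(x)), 0)
    semi <- vapply(1:3, function(a) 0.38 * diff(range(co[[a]])) + 1e-9, 0)
    for (l in seq_len(n_lesions)) {
      radius <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        # sample a mask voxel whose ellipsoidal depth leaves room for radius
        shrink <- pmax(semi - radius, 0.1)
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        cen <- ctr + u * shrink
        dx <- (grid_x - cen[1]); dy <- (grid_y - cen[2]); dz <- (grid_z - cen[3])
        d2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
        inside <- d2 <= radius^2 & mask
        if (any(inside)) {
          c1 <- fr[[1]]
          c1[inside] <- c1[inside] * config$lesion_c1_contrast
          tot <- c1 + fr[[2]] + fr[[3]] + fr[[4]]
          fr <- list(c1 / tot, fr[[2]] / tot, fr[[3]] / tot, fr[[4]] / tot)
          lesion_centers[[l]] <- cen
          placed <- TRUE
          break
        }
        radius <- radius * 0.8
      }
      if (!placed)
        stop("patient ", truth$patient_id,
             ": could not place lesion inside mask after ", max_attempts,
             " attempts")
    }
  }

  s0 <- 100 * (1 + 0.2 * smooth_field(dm))
  s0 <- pmax(s0, 1)
  decays <- exp(-outer(config$b_values, config$compartment_adcs))  # n_b x 4
  nb <- length(config$b_values)
  dwi <- array(0, dim = c(dm, nb))
  for (j in seq_len(nb)) {
    clean <- s0 * (fr[[1]] * decays[j, 1] + fr[[2]] * decays[j, 2] +
                   fr[[3]] * decays[j, 3] + fr[[4]] * decays[j, 4])
    dwi[, , , j] <- rician_noise(clean, truth$noise_sigma)
  }

  t2w <- 200 * (1 + 0.3 * smooth_field(dm))
  t2w <- rician_noise(pmax(t2w, 1), truth$noise_sigma)

  truth$lesion_centers <- lesion_centers
  truth$true_compartment_maps <- fr
  structure(
    list(patient_id = truth$patient_id, t2w = t2w, dwi = dwi,
         b_values = config$b_values, mask = mask,
         affine = config_affine(config), truth = truth),
    class = "imaging_study")
}

#' Generate and synthesize a full in-memory cohort
#'
#' Convenience wrapper: [generate_cohort()] then
#' [synthesize_patient_volumes()] for every patient.
#'
#' @inheritParams generate_cohort
#' @return List with `studies` (list of `imaging_study`), `manifest`, and
#'   `truths`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  gen <- generate_cohort(config, seed = seed)
  studies <- lapply(gen$truths, synthesize_patient_volumes, config = config)
  list(studies = studies, manifest = gen$manifest, truths = gen$truths)
}

nifti_with_spacing <- function(arr, affine) {
  img <- RNifti::asNifti(arr + 0)  # force numeric storage
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

#' Write a synthetic cohort to disk
#'
#' Layout: `manifest.csv` plus, per patient, `"<id>_t2w.nii.gz"`,
#' `"<id>_mask.nii.gz"`, and one `"<id>_dwi_b<b>.nii.gz"` per b-value; the
#' NIfTI affine encodes the voxel spacing.
#'
#' @param studies List of `imaging_study` objects.
#' @param manifest Cohort manifest data.frame.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(studies, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  for (st in studies) {
    pid <- st$patient_id
    RNifti::writeNifti(nifti_with_spacing(st$t2w, st$affine),
                       file.path(out_dir, paste0(pid, "_t2w.nii.gz")))
    RNifti::writeNifti(nifti_with_spacing(st$mask + 0, st$affine),
                       file.path(out_dir, paste0(pid, "_mask.nii.gz")))
    for (j in seq_along(st$b_values)) {
      fn <- sprintf("%s_dwi_b%g.nii.gz", pid, st$b_values[j])
      RNifti::writeNifti(nifti_with_spacing(st$dwi[, , , j], st$affine),
                         file.path(out_dir, fn))
    }
  }
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `studies` and `manifest`. Missing volumes raise an
#'   error listing the affected patients.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv under ", dir)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  missing <- character(0)
  studies <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pid <- manifest$patient_id[i]
    t2p <- file.path(dir, paste0(pid, "_t2w.nii.gz"))
    mkp <- file.path(dir, paste0(pid, "_mask.nii.gz"))
    dwp <- sort(Sys.glob(file.path(dir, paste0(pid, "_dwi_b*.nii.gz"))))
    if (!file.exists(t2p) || !file.exists(mkp) || length(dwp) == 0) {
      missing <- c(missing, pid)
      next
    }
    t2w <- RNifti::readNifti(t2p)
    bvals <- as.numeric(sub(".*_dwi_b([0-9.]+)\\.nii\\.gz$", "\\1", dwp))
    ord <- order(bvals)
    bvals <- bvals[ord]; dwp <- dwp[ord]
    vols <- lapply(dwp, RNifti::readNifti)
    dwi <- array(0, dim = c(dim(t2w), length(bvals)))
    for (j in seq_along(vols)) dwi[, , , j] <- vols[[j]]
    affine <- structure(RNifti::xform(t2w), code = NULL)
    studies[[i]] <- structure(
      list(patient_id = pid, t2w = as.array(t2w), dwi = dwi,
           b_values = bvals,
           mask = as.array(RNifti::readNifti(mkp)) > 0.5,
           affine = unclass(affine), truth = NULL),
      class = "imaging_study")
  }
  if (length(missing) > 0)
    stop("missing imaging files for patients: ", paste(missing, collapse = ", "))
  list(studies = studies, manifest = manifest)
}
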