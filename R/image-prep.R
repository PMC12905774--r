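## Channel preparation for the volumetric classifiers: resampling to the
## T2W grid, ADC and high-b derivation, crop/normalize, and augmentation.

## world -> voxel (0-based) using a 4x4 affine
world_to_voxel <- function(affine, xyz) {
  inv <- solve(affine)
  sweep(xyz, 2, inv[1:3, 4], `+`) %*% t(inv[1:3, 1:3])
}

## voxel (0-based) -> world
voxel_to_world <- function(affine, ijk) {
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

## Resample a source volume onto a target grid described by (dim, affine).
## Trilinear for intensities; "nearest" for masks/labels. Out-of-field
## voxels get 0; if no source voxel falls inside the target field of view
## the fields of view do not overlap.
resample_volume <- function(src, src_affine, target_dim, target_affine,
                            method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  ijk <- as.matrix(expand.grid(x = seq_len(target_dim[1]) - 1,
                               y = seq_len(target_dim[2]) - 1,
                               z = seq_len(target_dim[3]) - 1))
  world <- voxel_to_world(target_affine, ijk)
  svox <- world_to_voxel(src_affine, world)  # 0-based fractional
  d <- dim(src)
  inside <- svox[, 1] >= -0.5 & svox[, 1] <= d[1] - 0.5 &
            svox[, 2] >= -0.5 & svox[, 2] <= d[2] - 0.5 &
            svox[, 3] >= -0.5 & svox[, 3] <= d[3] - 0.5
  if (!any(inside))
    stop("non-overlapping fields of view: no target voxel maps into the source volume")
  out <- numeric(nrow(ijk))
  p <- svox[inside, , drop = FALSE]
  if (method == "nearest") {
    pi_ <- pmin(pmax(round(p) + 1, 1), matrix(d, nrow(p), 3, byrow = TRUE))
    out[inside] <- src[cbind(pi_[, 1], pi_[, 2], pi_[, 3])]
  } else {
    i0 <- pmin(pmax(floor(p), 0), matrix(d - 2, nrow(p), 3, byrow = TRUE))
    i0[, d == 1] <- 0
    w <- p - i0
    w <- pmin(pmax(w, 0), 1)
    acc <- numeric(nrow(p))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ix <- pmin(i0[, 1] + dx + 1, d[1])
      iy <- pmin(i0[, 2] + dy + 1, d[2])
      iz <- pmin(i0[, 3] + dz + 1, d[3])
      wt <- (if (dx == 0) 1 - w[, 1] else w[, 1]) *
            (if (dy == 0) 1 - w[, 2] else w[, 2]) *
            (if (dz == 0) 1 - w[, 3] else w[, 3])
      acc <- acc + wt * src[cbind(ix, iy, iz)]
    }
    out[inside] <- acc
  }
  array(out, dim = target_dim)
}

#' Resample all modalities of a study onto the T2W grid
#'
#' DWI volumes (and any ADC/high-b maps already present) are trilinearly
#' interpolated onto the T2W grid; the prostate mask is resampled
#' nearest-neighbor and re-binarized. Studies already on a common grid pass
#' through unchanged up to float tolerance.
#'
#' @param study An `imaging_study` whose elements may carry their own
#'   affines in `study$affines` (named list); defaults to the shared
#'   `study$affine` when absent.
#' @return The study with every volume on the T2W grid.
#' @export
resample_to_t2w <- function(study) {
  tdim <- dim(study$t2w)
  taff <- study$affine
  aff_of <- function(name) {
    if (!is.null(study$affines) && !is.null(study$affines[[name]]))
      study$affines[[name]] else study$affine
  }
  nb <- dim(study$dwi)[4]
  dwi <- array(0, dim = c(tdim, nb))
  for (j in seq_len(nb))
    dwi[, , , j] <- resample_volume(study$dwi[, , , j], aff_of("dwi"),
                                    tdim, taff, "trilinear")
  study$dwi <- dwi
  study$mask <- resample_volume(study$mask + 0, aff_of("mask"),
                                tdim, taff, "nearest") > 0.5
  if (!is.null(study$adc))
    study$adc <- resample_volume(study$adc, aff_of("adc"), tdim, taff, "trilinear")
  study$affines <- NULL
  study
}

#' Apparent diffusion coefficient by mono-exponential fit
#'
#' Per-voxel slope of `-log(S)` against b over the selected b-values,
#' obtained in closed form by least squares. Nonpositive signals are clamped
#' to a small epsilon before the log so degenerate voxels stay finite.
#'
#' @param dwi 4-D DWI array (x, y, z, b).
#' @param b_values b-values matching the 4th axis.
#' @param b_subset b-values used for the fit; defaults to `b <= 1000`
#'   (conventional clinical ADC range).
#' @param eps Clamp floor for the signal.
#' @return ADC volume in mm^2/s.
#' @export
compute_adc <- function(dwi, b_values, b_subset = b_values[b_values <= 1000],
                        eps = 1e-6) {
  use <- which(b_values %in% b_subset)
  if (length(use) < 2) stop("need at least 2 b-values for the ADC fit")
  b <- b_values[use]
  dm <- dim(dwi)[1:3]
  logS <- sapply(use, function(j) log(pmax(as.vector(dwi[, , , j]), eps)))
  bc <- b - mean(b)
  slope <- as.vector(logS %*% bc) / sum(bc^2)
  array(-slope, dim = dm)
}

#' Highest-b-value DWI volume
#'
#' The "high-b" channel fed to the classifiers is the acquired volume with
#' the largest b-value.
#'
#' @inheritParams compute_adc
#' @return The volume at `max(b_values)`.
#' @export
select_high_b <- function(dwi, b_values) {
  if (length(b_values) == 0 || length(dim(dwi)) != 4)
    stop("empty DWI stack")
  dwi[, , , which.max(b_values)]
}

mask_bounding_box <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty mask: no bounding box")
  rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
}

## center crop/pad a volume to shape, centered at ctr (1-based voxel coords)
crop_pad <- function(vol, ctr, shape) {
  out <- array(0, dim = shape)
  d <- dim(vol)
  start <- round(ctr - shape / 2)          # 0-based start
  src_lo <- pmax(start + 1, 1)
  src_hi <- pmin(start + shape, d)
  dst_lo <- src_lo - start
  dst_hi <- dst_lo + (src_hi - src_lo)
  if (any(src_hi < src_lo)) return(out)
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    vol[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Assemble the normalized multi-channel input tensor for a classifier
#'
#' Channels are cropped (or zero-padded) to `crop_shape` centered on the
#' prostate-mask bounding box, then z-scored per channel using statistics
#' computed inside the bounding box (standard deviation floored so constant
#' channels map to zero). Channel order is fixed: bpMRI = (t2w, adc,
#' high_b); bpMRI+RSI appends (rsi_c1, rsi_c2).
#'
#' @param study An `imaging_study` (all volumes on the T2W grid).
#' @param rsi_maps A `compartment_maps` object (required for
#'   `channel_set = "bpmri_rsi"`).
#' @param channel_set `"bpmri"` (3 channels) or `"bpmri_rsi"` (5 channels).
#' @param crop_shape Output spatial shape.
#' @param rsirs_max_value Optional scalar biomarker carried on the tensor.
#' @return A `model_input` list: `array` (channel, x, y, z), `channels`,
#'   `rsirs_max`.
#' @export
assemble_input <- function(study, rsi_maps = NULL,
                           channel_set = c("bpmri", "bpmri_rsi"),
                           crop_shape = c(16L, 16L, 12L),
                           rsirs_max_value = NULL) {
  channel_set <- match.arg(channel_set)
  if (is.null(study$adc))
    study$adc <- compute_adc(study$dwi, study$b_values)
  if (is.null(study$high_b))
    study$high_b <- select_high_b(study$dwi, study$b_values)
  chans <- list(t2w = study$t2w, adc = study$adc, high_b = study$high_b)
  if (channel_set == "bpmri_rsi") {
    if (is.null(rsi_maps))
      stop("channel 'rsi_c1' requested but rsi_maps is missing")
    chans$rsi_c1 <- rsi_maps$c1
    chans$rsi_c2 <- rsi_maps$c2
  }
  bb <- mask_bounding_box(study$mask)
  ctr <- colMeans(bb)
  arr <- array(0, dim = c(length(chans), crop_shape))
  for (k in seq_along(chans)) {
    v <- chans[[k]]
    box <- v[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3]]
    mu <- mean(box)
    sdv <- max(sd(as.vector(box)), 1e-6)
    arr[k, , , ] <- crop_pad((v - mu) / sdv, ctr, crop_shape)
  }
  structure(list(array = arr, channels = names(chans),
                 rsirs_max = rsirs_max_value),
            class = "model_input")
}

#' Default label-safe augmentation policy
#'
#' @param flip Enable random left-right flip.
#' @param max_translate Maximum absolute integer translation per axis, voxels.
#' @param jitter_sd Standard deviation of the multiplicative intensity
#'   jitter (0 disables).
#' @return An `augment_policy` list.
#' @export
augment_policy <- function(flip = TRUE, max_translate = 2L, jitter_sd = 0.05) {
  structure(list(flip = flip, max_translate = as.integer(max_translate),
                 jitter_sd = jitter_sd), class = "augment_policy")
}

#' Randomly augment a model input tensor
#'
#' Applies (under the current RNG state, so a fixed seed replays the same
#' transforms) a random left-right flip, small integer translations, and
#' mild multiplicative intensity jitter. All transforms preserve the label
#' and the `rsirs_max` scalar. An empty policy is the identity.
#'
#' @param tensor A `model_input`.
#' @param policy An [augment_policy()]; `NULL` disables augmentation.
#' @return Augmented `model_input`.
#' @export
augment <- function(tensor, policy = augment_policy()) {
  if (is.null(policy)) return(tensor)
  a <- tensor$array
  dm <- dim(a)
  if (isTRUE(policy$flip) && runif(1) < 0.5)
    a <- a[, rev(seq_len(dm[2])), , , drop = FALSE]
  if (policy$max_translate > 0) {
    sh <- sample(seq(-policy$max_translate, policy$max_translate), 3, replace = TRUE)
    for (ax in 1:3) {
      if (sh[ax] == 0) next
      n <- dm[ax + 1]
      idx <- seq_len(n) - sh[ax]
      pad <- idx < 1 | idx > n
      idx <- pmin(pmax(idx, 1), n)
      if (ax == 1) { a <- a[, idx, , , drop = FALSE]; a[, pad, , ] <- 0 }
      if (ax == 2) { a <- a[, , idx, , drop = FALSE]; a[, , pad, ] <- 0 }
      if (ax == 3) { a <- a[, , , idx, drop = FALSE]; a[, , , pad] <- 0 }
    }
  }
  if (policy$jitter_sd > 0) {
    g <- rnorm(dm[1], mean = 1, sd = policy$jitter_sd)
    a <- a * g  # recycles over the channel axis (first dimension)
  }
  tensor$array <- a
  tensor
}
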