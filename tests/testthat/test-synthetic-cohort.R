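test_that("cohort generation is deterministic and respects site parameters", {
  cfg <- tiny_cohort_config(n = 10, seed = 5)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$manifest, g2$manifest)
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(g1$manifest, f1, row.names = FALSE)
  write.csv(g2$manifest, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  cfg0 <- cohort_config(sites = list(site_profile("z", 25, 0, 0.5)),
                        seed = 3)
  g0 <- generate_cohort(cfg0)
  expect_true(all(g0$manifest$cspca_label == 0))
})

test_that("observed csPCa prevalence matches the configured rate at large n", {
  prev <- 0.39
  cfg <- cohort_config(sites = list(site_profile("big", 2000, prev, 0.5)),
                       seed = 11)
  g <- generate_cohort(cfg)
  se <- sqrt(prev * (1 - prev) / 2000)
  expect_lt(abs(mean(g$manifest$cspca_label) - prev), 3 * se)
})

test_that("invalid probability vectors raise an error naming the site", {
  expect_error(site_profile("bad_site", 5, 0.3, 0.5,
                            pirads_given_cspca = c(0.5, 0.5, 0.5, 0, 0)),
               "bad_site")
  expect_error(site_profile("s", 5, 1.2, 0.5), "prevalence")
})

test_that("PI-RADS draws follow the label-conditional distributions", {
  pir <- default_pirads_conditionals()
  cfg <- cohort_config(sites = list(site_profile("p", 5000, 0.5, 0.5)),
                       seed = 21)
  g <- generate_cohort(cfg)
  for (lab in 0:1) {
    sel <- g$manifest$cspca_label == lab
    obs <- tabulate(g$manifest$pirads[sel], 5)
    expected <- if (lab == 1) pir$cspca else pir$benign
    gof <- suppressWarnings(chisq.test(obs, p = expected))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("forward model obeys closed forms at zero noise", {
  cfg <- tiny_cohort_config(n = 2, noise_sigma = 0, seed = 9)
  g <- generate_cohort(cfg)
  st <- synthesize_patient_volumes(g$truths[[1]], cfg)
  # fractions sum to one everywhere (conservation)
  tot <- Reduce(`+`, st$truth$true_compartment_maps)
  expect_equal(max(abs(tot - 1)), 0, tolerance = 1e-12)
  # b = 0: exp(0) = 1 for every compartment, so signal at b = 0 equals S0,
  # and the signal at any b is S0 times the fraction-weighted decay
  dec <- exp(-outer(cfg$b_values, cfg$compartment_adcs))
  s0 <- st$dwi[, , , 1]
  for (j in seq_along(cfg$b_values)) {
    pred <- s0 * Reduce(`+`, Map(function(f, d) f * d,
                                 st$truth$true_compartment_maps,
                                 as.list(dec[j, ]))) /
      Reduce(`+`, Map(function(f, d) f * d,
                      st$truth$true_compartment_maps, as.list(dec[1, ])))
    expect_equal(st$dwi[, , , j], pred, tolerance = 1e-10)
  }
})

test_that("single-compartment signal decays log-linearly with slope -D1", {
  cfg <- cohort_config(sites = list(site_profile("s", 1, 0, 0.5, noise_sigma = 0)),
                       background_fractions = c(1, 0, 0, 0),
                       grid_shape = c(8L, 8L, 6L), seed = 2)
  g <- generate_cohort(cfg)
  st <- synthesize_patient_volumes(g$truths[[1]], cfg)
  v <- st$dwi[4, 4, 3, ]
  slope <- coef(lm(log(v) ~ cfg$b_values))[2]
  expect_equal(unname(slope), -cfg$compartment_adcs[1], tolerance = 1e-9)
})

test_that("lesions elevate the restricted fraction above matched background", {
  cfg <- tiny_cohort_config(n = 6, prevalence = 1, noise_sigma = 0, seed = 13)
  g <- generate_cohort(cfg)
  for (tr in g$truths[1:3]) {
    st <- synthesize_patient_volumes(tr, cfg)
    c1 <- st$truth$true_compartment_maps[[1]]
    bg_c1 <- cfg$background_fractions[1]
    # lesion voxels: restricted fraction well above the background band
    expect_gt(max(c1[st$mask]), bg_c1 * 2)
    expect_gt(length(st$truth$lesion_centers), 0)
  }
})

test_that("noiseless restriction score separates csPCa from benign patients", {
  cfg <- tiny_cohort_config(n = 14, prevalence = 0.5, noise_sigma = 0, seed = 17)
  sim <- simulate_cohort(cfg)
  fc <- rsi_fit_config(b_values = cfg$b_values,
                       compartment_adcs = cfg$compartment_adcs)
  rs <- vapply(sim$studies, function(s) rsi_biomarker(s, fc)$rsirs_max, 0)
  y <- sim$manifest$cspca_label
  skip_if(length(unique(y)) < 2)
  expect_gt(min(rs[y == 1]), max(rs[y == 0]))
})

test_that("cohort round-trips through NIfTI files", {
  cfg <- tiny_cohort_config(n = 3, noise_sigma = 0.5, seed = 4,
                            grid = c(10L, 10L, 8L))
  sim <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(sim$studies, sim$manifest, d)
  back <- read_cohort(d)
  expect_identical(back$manifest, sim$manifest)
  expect_equal(back$studies[[1]]$dwi, sim$studies[[1]]$dwi,
               tolerance = 1e-6)
  expect_identical(back$studies[[2]]$mask, sim$studies[[2]]$mask)
  # affine carries the voxel spacing
  expect_equal(diag(back$studies[[1]]$affine)[1:3], cfg$voxel_spacing)
})

test_that("reading a cohort with missing volumes names the absent patients", {
  cfg <- tiny_cohort_config(n = 3, seed = 6, grid = c(8L, 8L, 6L))
  sim <- simulate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(sim$studies, sim$manifest, d)
  pid <- sim$manifest$patient_id[2]
  file.remove(file.path(d, paste0(pid, "_mask.nii.gz")))
  expect_error(read_cohort(d), pid)
})
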