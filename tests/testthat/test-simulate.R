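test_that("generation is bit-identical under a fixed seed", {
  a <- list(analyte_spec("C7H8O2", rt = 5, intensity = 2e5),
            analyte_spec("C6H5NO3", rt = 3, intensity = 5e5))
  r1 <- make_run(a, noise_spec(seed = 7))
  r2 <- make_run(a, noise_spec(seed = 7))
  expect_identical(r1$run$centroids, r2$run$centroids)
  expect_identical(r1$truth, r2$truth)
  r3 <- make_run(a, noise_spec(seed = 8))
  expect_false(identical(r1$run$centroids, r3$run$centroids))
  # the caller's RNG stream is untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(make_run(a, noise_spec(seed = 7)))
  expect_identical(runif(1), before)
})

test_that("a noise-free analyte yields an exact sampled Gaussian", {
  a <- analyte_spec("C7H8O2", rt = 5, width = 0.05, intensity = 1e5)
  sim <- make_run(list(a), noise_spec(background_density = 0,
                                      ppm_jitter = 0, intensity_cv = 0,
                                      seed = 1), rt_range = c(0, 10))
  eic <- extract_eic(sim$run, window_for(123.0452, "accurate"))
  expected <- 1e5 * exp(-(eic$rt - 5)^2 / (2 * 0.05^2))
  expected[expected < 1] <- 0
  expect_equal(eic$intensity, expected, tolerance = 1e-9)
  # integrated area within 2% of the analytic Gaussian area
  area <- integrate_peak(eic, c(4.7, 5.3))
  expect_equal(area, sim$truth$area[1], tolerance = 0.02)
})

test_that("generated isotopologue ratios match theory", {
  a <- analyte_spec("C16H26O3S", rt = 4, intensity = 1e6)
  sim <- make_run(list(a), noise_spec(background_density = 0,
                                      ppm_jitter = 0, intensity_cv = 0,
                                      seed = 1), rt_range = c(0, 8))
  th <- isotope_pattern(parse_formula("C16H26O3S"), "[M-H]-")
  apex_scan <- which.min(abs(sim$run$rt - 4))
  cen <- sim$run$centroids[sim$run$centroids$scan == apex_scan, ]
  get_at <- function(mz) sum(cen$intensity[abs(cen$mz - mz) < 0.01])
  a0 <- get_at(th$mz[1]); a1 <- get_at(th$mz[2]); a2 <- get_at(th$mz[3])
  expect_equal(a1 / a0, th$rel[2], tolerance = 0.01)
  expect_equal(a2 / a0, th$rel[3], tolerance = 0.01)
})

test_that("blank fixtures drive the downstream ratio rule", {
  art <- analyte_spec("C8H18O3", rt = 7, intensity = 2e5,
                      name = "contaminant")
  bl <- make_blank(list(art), noise_spec(seed = 31), rt_range = c(0, 9))
  expect_identical(bl$run$role, "solvent_blank")
  # sample carrying 2x the blank area is removed at threshold 3;
  # a 10x sample survives
  art2 <- art; art2$intensity <- 2 * art$intensity
  art10 <- art; art10$intensity <- 10 * art$intensity
  s2 <- make_run(list(art2), noise_spec(seed = 32), rt_range = c(0, 9))
  s10 <- make_run(list(art10), noise_spec(seed = 33), rt_range = c(0, 9))
  fb <- detect_features(bl$run)
  f2 <- detect_features(s2$run)
  f10 <- detect_features(s10$run)
  expect_equal(nrow(blank_subtract(f2, fb)$retained), 0)
  expect_equal(nrow(blank_subtract(f10, fb)$retained), 1)
  # empty artifact list gives a noise-only blank
  noiseonly <- make_blank(list(), noise_spec(seed = 34))
  expect_equal(nrow(detect_features(noiseonly$run)), 0)
})

test_that("calibration series scales apex with concentration", {
  a <- analyte_spec("C7H8O2", rt = 2, intensity = 1, width = 0.05)
  concs <- c(0.01, 0.05, 0.2, 1, 5)
  series <- make_calibration_series(a, concs, response_factor = 2e5,
                                    noise = noise_spec(
                                      seed = 5, background_density = 0.05,
                                      intensity_cv = 0.02),
                                    rt_range = c(0, 4))
  expect_equal(length(series), 15)
  areas <- vapply(series, function(s) {
    pk <- detect_peaks(extract_eic(s$run,
                                   window_for(123.0452, "accurate")),
                       min_intensity = 0, min_sn = 0, min_scans = 3)
    if (nrow(pk)) max(pk$area) else 0
  }, numeric(1))
  df <- data.frame(concentration = vapply(series, `[[`, numeric(1),
                                          "concentration"),
                   area = areas)
  cal <- fit_calibration(df)
  expect_gt(cal$r_squared, 0.99)
  # dropouts: sub-threshold levels never reach the minimum peak intensity
  low <- make_calibration_series(a, c(0.01, 0.02, 0.05, 0.1, 0.2),
                                 response_factor = 2e5,
                                 noise = noise_spec(seed = 6,
                                                    background_density = 0),
                                 rt_range = c(0, 4))
  low_apex <- vapply(low, function(s) s$truth$apex[1], numeric(1))
  detected <- vapply(low, function(s) {
    nrow(detect_peaks(extract_eic(s$run,
                                  window_for(123.0452, "accurate")))) > 0
  }, logical(1))
  expect_true(all(!detected[low_apex < 3e4]))
  expect_true(any(detected[low_apex > 3e4]))
})

test_that("interference strictly degrades only the unit-mode S/N", {
  base <- interference_fixture(ridge_mean = 0, ridge_sd = 0)
  inter <- interference_fixture()
  sn_u0 <- sn_for_species(base$run, 123.0452, "unit")$sn
  sn_u1 <- sn_for_species(inter$run, 123.0452, "unit")$sn
  sn_a0 <- sn_for_species(base$run, 123.0452, "accurate")$sn
  sn_a1 <- sn_for_species(inter$run, 123.0452, "accurate")$sn
  expect_lt(sn_u1, sn_u0)
  # accurate-mode S/N unchanged within noise (same infinite/finite class
  # or within 20%)
  if (is.finite(sn_a0) && is.finite(sn_a1)) {
    expect_equal(sn_a1, sn_a0, tolerance = 0.2)
  } else {
    expect_identical(is.finite(sn_a0), is.finite(sn_a1))
  }
})
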