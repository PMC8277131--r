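# small hand-built helpers
eic_of <- function(rt, intensity) {
  structure(list(rt = rt, intensity = intensity,
                 window = mz_window(0, 1000)), class = "nts_eic")
}

run_of <- function(rt, centroids) {
  new_run(rt, centroids, polarity = "negative")
}

test_that("EIC windows sum in-window centroids, half-open on the right", {
  run <- run_of(c(1, 2), data.frame(
    scan = c(1, 1, 2), mz = c(123.045, 123.98, 124.0),
    intensity = c(1e5, 4e4, 2e4)))
  unit <- extract_eic(run, mz_window(123, 124, "unit"))
  expect_equal(unit$intensity, c(1.4e5, 0))
  acc <- extract_eic(run, mz_window(123.0450, 123.0460))
  expect_equal(acc$intensity, c(1e5, 0))
  # 124.0 belongs to the next unit window
  nxt <- extract_eic(run, mz_window(124, 125, "unit"))
  expect_equal(nxt$intensity, c(0, 2e4))
})

test_that("narrowing a window never increases any scan's EIC value", {
  set.seed(41)
  run <- run_of(1:20, data.frame(
    scan = sample(1:20, 300, replace = TRUE),
    mz = runif(300, 100, 110), intensity = rexp(300, 1e-3)))
  wide <- extract_eic(run, mz_window(100, 110))
  for (i in 1:10) {
    lo <- runif(1, 100, 105); hi <- runif(1, lo + 0.1, 110)
    narrow <- extract_eic(run, mz_window(lo, hi))
    expect_true(all(narrow$intensity <= wide$intensity + 1e-9))
  }
})

test_that("noise estimate is robust, deterministic and correctly scaled", {
  expect_equal(estimate_noise(eic_of(1:20, rep(7, 20))), 0)
  n <- 50
  alt <- eic_of(1:20, rep(c(0, 2 * n), 10))
  expect_equal(estimate_noise(alt), n * 1.4826, tolerance = 1e-9)
  set.seed(5)
  g <- eic_of(seq(0, 10, length.out = 500), abs(rnorm(500, 1000, 100)))
  expect_equal(estimate_noise(g), 100, tolerance = 0.15)
  expect_error(estimate_noise(eic_of(1:5, rep(1, 5))), "baseline")
  # exclusion interval removes a peak's own region
  y <- rep(10, 100); y[40:60] <- 1e5
  e <- eic_of(seq_len(100), y)
  expect_equal(estimate_noise(e, exclusion = c(35, 65)), 0)
})

test_that("peak detection applies the S/N, intensity and scan-count gates", {
  rt <- seq(0, 10, by = 1 / 60)
  gauss <- function(apex) apex * exp(-(rt - 5)^2 / (2 * 0.05^2))
  set.seed(9)
  noise <- abs(rnorm(length(rt), 1e3, 1e3))
  pk <- detect_peaks(eic_of(rt, gauss(5e4) + noise))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$apex_rt, 5, tolerance = 0.05)
  expect_equal(pk$sn, 50, tolerance = 0.4 * 50)
  expect_gt(pk$sn, 10)
  # below the minimum intensity: no peak
  expect_equal(nrow(detect_peaks(eic_of(rt, gauss(2e4) + noise))), 0)
  # a 2-scan spike fails the consecutive-scan rule
  spike <- noise; spike[300:301] <- 1e6
  expect_equal(nrow(detect_peaks(eic_of(rt, spike), min_scans = 3)), 0)
})

test_that("peak count is monotone non-increasing in every threshold", {
  rt <- seq(0, 20, by = 1 / 60)
  set.seed(17)
  y <- abs(rnorm(length(rt), 500, 500))
  for (ap in c(4e4, 8e4, 2e5, 1e6)) {
    ctr <- runif(1, 2, 18)
    y <- y + ap * exp(-(rt - ctr)^2 / (2 * 0.04^2))
  }
  eic <- eic_of(rt, y)
  base <- nrow(detect_peaks(eic))
  for (sn in c(3, 10, 50, 200)) {
    expect_lte(nrow(detect_peaks(eic, min_sn = sn)), base)
  }
  prev <- Inf
  for (mi in c(3e4, 1e5, 5e5, 2e6)) {
    n <- nrow(detect_peaks(eic, min_intensity = mi))
    expect_lte(n, prev); prev <- n
  }
  expect_lte(nrow(detect_peaks(eic, min_scans = 10)),
             nrow(detect_peaks(eic, min_scans = 3)))
})

test_that("detection is invariant to uniform intensity scaling", {
  rt <- seq(0, 10, by = 1 / 60)
  set.seed(19)
  y <- abs(rnorm(length(rt), 800, 800)) +
    6e4 * exp(-(rt - 4)^2 / (2 * 0.05^2)) +
    2e5 * exp(-(rt - 7)^2 / (2 * 0.05^2))
  p1 <- detect_peaks(eic_of(rt, y), min_intensity = 3e4)
  p2 <- detect_peaks(eic_of(rt, 10 * y), min_intensity = 3e5)
  expect_equal(nrow(p1), nrow(p2))
  expect_equal(p1$apex_rt, p2$apex_rt)
  expect_equal(p2$area, 10 * p1$area, tolerance = 1e-9)
  expect_equal(p2$sn, p1$sn, tolerance = 1e-9)
})

test_that("trapezoidal integration matches closed forms and is linear", {
  rt <- seq(0, 1, by = 0.01)
  rect <- eic_of(rt, rep(100, length(rt)))
  expect_equal(integrate_peak(rect, c(0.2, 0.7)), 100 * 0.5,
               tolerance = 1e-9)
  tri <- eic_of(c(0, 0.5, 1), c(0, 100, 0))
  expect_equal(integrate_peak(tri, c(0, 1)), 100 * 1 / 2)
  y <- abs(sin(rt * 7)) * 50
  e1 <- eic_of(rt, y); e2 <- eic_of(rt, 2 * y)
  expect_equal(integrate_peak(e2, c(0.1, 0.9)),
               2 * integrate_peak(e1, c(0.1, 0.9)))
  expect_error(integrate_peak(rect, c(0.7, 0.2)), "inverted")
})

test_that("accurate-mass S/N beats unit-mass S/N under interference", {
  fx <- interference_fixture()
  su <- sn_for_species(fx$run, 123.0452, "unit")
  sa <- sn_for_species(fx$run, 123.0452, "accurate")
  expect_gt(sa$sn, su$sn)
  # without interference the two modes agree within noise-estimate error
  a <- analyte_spec("C7H8O2", rt = 5, intensity = 5e5)
  clean <- make_run(list(a), noise_spec(seed = 2, background_density = 2,
                                        background_intensity = 500),
                    rt_range = c(0, 10))
  su2 <- sn_for_species(clean$run, 123.0452, "unit")
  expect_gt(su2$sn, 3)
  # noise-free run reports the sentinel
  pure <- make_run(list(a), noise_spec(seed = 3, background_density = 0,
                                       intensity_cv = 0, ppm_jitter = 0))
  expect_true(is.infinite(
    sn_for_species(pure$run, 123.0452, "accurate")$sn))
  expect_error(sn_for_species(pure$run, 400.1, "accurate"), "no signal")
})

test_that("alignment recovers a global RT shift with a monotone warp", {
  analytes <- lapply(seq(1, 9, by = 2), function(r) {
    analyte_spec(formula_of(C = 10 + r, H = 12 + 2 * r, O = 4), rt = r,
                 intensity = 5e5)
  })
  ref <- make_run(analytes, noise_spec(seed = 21), rt_range = c(0, 10))
  shifted <- ref$run
  shifted$rt <- shifted$rt + 0.3
  al <- align_runs(list(ref$run, shifted))
  expect_gte(al$summary$n_anchors[2], 3)
  # the warp maps shifted RT back to reference RT
  grid <- seq(1, 9, by = 0.5)
  err_before <- abs((grid + 0.3) - grid)
  err_after <- abs(al$warps[[2]](grid + 0.3) - grid)
  expect_lt(median(err_after), 0.2 * median(err_before))
  # monotone
  w <- al$warps[[2]](seq(0, 10.3, by = 0.05))
  expect_true(all(diff(w) >= -1e-9))
  # run vs itself: identity
  al2 <- align_runs(list(ref$run, ref$run))
  expect_equal(al2$warps[[2]](c(2, 5, 8)), c(2, 5, 8), tolerance = 1e-6)
})

test_that("feature detection recovers ground truth with high precision", {
  set.seed(43)
  analytes <- lapply(1:12, function(i) {
    analyte_spec(random_legal_formula(), rt = 0.5 + i * 0.7,
                 intensity = runif(1, 2e5, 1e6))
  })
  sim <- make_run(analytes, noise_spec(seed = 43), rt_range = c(0, 10),
                  mz_range = c(60, 450))
  ft <- detect_features(sim$run)
  truth <- sim$truth
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(ft$mz - truth$mz[i]) <= truth$mz[i] * 5e-6 &
          abs(ft$rt - truth$rt[i]) <= 0.1)
  }, logical(1))
  expect_gte(mean(matched), 0.95)
  spurious <- vapply(seq_len(nrow(ft)), function(i) {
    !any(abs(truth$mz - ft$mz[i]) <= ft$mz[i] * 5e-6 &
           abs(truth$rt - ft$rt[i]) <= 0.1)
  }, logical(1))
  expect_gte(1 - mean(spurious), 0.95)
})
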