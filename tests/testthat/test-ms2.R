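spec2 <- function(mz, intensity, precursor = 200, rt = NA_real_) {
  ms2_spectrum(data.frame(mz = mz, intensity = intensity),
               precursor_mz = precursor, rt = rt)
}

test_that("spectral similarity hits the 0/50/100 landmarks", {
  a <- spec2(c(80.1, 119.2, 183.0), c(30, 60, 100))
  expect_equal(spectral_similarity(a, a), 100)
  b <- spec2(c(55.0, 91.3), c(10, 20))
  expect_equal(spectral_similarity(a, b), 0)
  p <- spec2(c(100, 150), c(1, 1))
  q <- spec2(c(100, 200), c(1, 1))
  expect_equal(spectral_similarity(p, q), 50)
})

test_that("similarity is symmetric and scale-invariant", {
  set.seed(73)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- spec2(sort(runif(n1, 50, 190)), runif(n1, 1, 100))
    b <- spec2(sort(runif(n2, 50, 190)), runif(n2, 1, 100))
    expect_equal(spectral_similarity(a, b), spectral_similarity(b, a),
                 tolerance = 1e-9)
    a10 <- spec2(a$fragments$mz, a$fragments$intensity * 10)
    expect_equal(spectral_similarity(a10, b), spectral_similarity(a, b),
                 tolerance = 1e-9)
  }
  # 100 only when matched and proportional with no unmatched intensity
  a <- spec2(c(100, 150), c(2, 4))
  prop <- spec2(c(100, 150), c(1, 2))
  expect_equal(spectral_similarity(a, prop), 100, tolerance = 1e-9)
  extra <- spec2(c(100, 150, 180), c(2, 4, 1))
  expect_lt(spectral_similarity(a, extra), 100)
})

test_that("library search ranks, filters and ignores library order", {
  frag <- data.frame(mz = c(80.96, 119.05, 183.01),
                     intensity = c(30, 60, 100))
  f <- parse_formula("C16H26O3S")
  mk <- function(name, scale) {
    library_entry(name, f,
                  ms2_spectrum(transform(frag, intensity = intensity * scale),
                               precursor_mz = ion_mz(f, "[M-H]-"),
                               species = "[M-H]-", rt = 4), rt = 4)
  }
  other <- library_entry("decoy", "C7H8O2",
                         ms2_spectrum(data.frame(mz = c(77.0, 108.0),
                                                 intensity = c(50, 100)),
                                      precursor_mz = 123.0452,
                                      species = "[M-H]-", rt = 6), rt = 6)
  lib <- list(mk("las", 1), other)
  q <- ms2_spectrum(frag, precursor_mz = ion_mz(f, "[M-H]-"), rt = 4.1)
  hits <- search_library(q, lib)
  expect_equal(hits$compound[1], "las")
  expect_equal(hits$score[1], 100)
  # precursor 50 ppm off everything: empty
  far <- ms2_spectrum(frag, precursor_mz = ion_mz(f, "[M-H]-") * (1 + 5e-5))
  expect_equal(nrow(search_library(far, lib)), 0)
  # noisy copy still matches at high score
  set.seed(79)
  noisy <- ms2_spectrum(transform(frag,
                                  intensity = intensity * runif(3, 0.9, 1.1)),
                        precursor_mz = ion_mz(f, "[M-H]-"), rt = 4)
  nh <- search_library(noisy, lib)
  expect_equal(nh$compound[1], "las")
  expect_gt(nh$score[1], 95)
  # shuffling the library changes nothing
  h2 <- search_library(q, rev(lib))
  expect_identical(hits, h2)
})

test_that("confidence levels follow the five-level scheme monotonically", {
  expect_equal(assign_confidence(FALSE), 5L)
  expect_equal(assign_confidence(TRUE, has_ms2 = FALSE), 4L)
  expect_equal(assign_confidence(TRUE, has_ms2 = TRUE), 3L)
  expect_equal(assign_confidence(TRUE, has_ms2 = TRUE, match_score = 92), 2L)
  expect_equal(assign_confidence(TRUE, has_ms2 = TRUE, match_score = 92,
                                 rt_deviation = 0.2), 1L)
  # below-threshold match does not reach level 2
  expect_equal(assign_confidence(TRUE, has_ms2 = TRUE, match_score = 70), 3L)
  # adding evidence never increases the level
  lvls <- c(assign_confidence(FALSE),
            assign_confidence(TRUE),
            assign_confidence(TRUE, has_ms2 = TRUE),
            assign_confidence(TRUE, has_ms2 = TRUE, match_score = 95),
            assign_confidence(TRUE, has_ms2 = TRUE, match_score = 95,
                              rt_deviation = 0.1))
  expect_true(all(diff(lvls) <= 0))
})

test_that("MSP and MGF round-trip libraries and spectra", {
  f <- parse_formula("C6H5NO3")
  entries <- list(
    library_entry("nitrophenol", f,
                  ms2_spectrum(data.frame(mz = c(46.01, 108.02),
                                          intensity = c(100, 40)),
                               precursor_mz = ion_mz(f, "[M-H]-"),
                               species = "[M-H]-", rt = 2.5),
                  rt = 2.5, source_category = "biomass_burning"),
    library_entry("catechol_methyl", "C7H8O2",
                  ms2_spectrum(data.frame(mz = c(77.04, 123.04),
                                          intensity = c(20, 100)),
                               precursor_mz = 123.0452,
                               species = "[M-H]-", rt = 6.0), rt = 6.0))
  msp <- file.path(tempdir(), "lib.msp")
  write_msp(entries, msp)
  back <- read_msp(msp)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$name, "nitrophenol")
  expect_equal(format_formula(back[[1]]$formula), "C6H5NO3")
  expect_equal(back[[1]]$rt, 2.5, tolerance = 1e-6)
  expect_equal(back[[1]]$source_category, "biomass_burning")
  expect_equal(back[[2]]$spectrum$fragments$mz,
               entries[[2]]$spectrum$fragments$mz, tolerance = 1e-6)
  sp <- list(q1 = entries[[1]]$spectrum, q2 = entries[[2]]$spectrum)
  mgf <- file.path(tempdir(), "spec.mgf")
  write_mgf(sp, mgf)
  back2 <- read_mgf(mgf)
  expect_setequal(names(back2), c("q1", "q2"))
  expect_equal(back2$q1$precursor_mz, sp$q1$precursor_mz,
               tolerance = 1e-6)
  expect_equal(back2$q2$fragments$intensity, sp$q2$fragments$intensity,
               tolerance = 1e-3)
  expect_equal(back2$q1$rt, 2.5, tolerance = 1e-4)
})

test_that("library entries validate precursor/formula consistency", {
  f <- parse_formula("C7H8O2")
  bad <- ms2_spectrum(data.frame(mz = 77, intensity = 1),
                      precursor_mz = 140.00, species = "[M-H]-")
  expect_error(library_entry("x", f, bad), "inconsistent")
  expect_error(ms2_spectrum(data.frame(mz = 500, intensity = 1),
                            precursor_mz = 123), "above precursor")
})
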