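test_that("element limits encode the per-mode defaults", {
  pm <- element_limits("negative_pm")
  expect_equal(pm$max[["N"]], 5)
  expect_equal(pm$max[["S"]], 2)
  expect_equal(pm$max[["Cl"]], 0)
  expect_true(is.infinite(pm$max[["C"]]))
  expect_equal(element_limits("negative_water")$max[["Cl"]], 3)
  pos <- element_limits("positive", allow_metals = TRUE)
  expect_equal(pos$max[["Na"]], 2)
  expect_equal(pos$max[["K"]], 1)
  expect_equal(element_limits("positive")$max[["Na"]], 0)
})

test_that("candidate enumeration finds the reference deprotonated diol", {
  cand <- enumerate_candidates(123.0452, "[M-H]-",
                               element_limits("negative_pm"), 3)
  expect_true("C7H8O2" %in% cand$formula)
  expect_true(all(abs(cand$ppm) < 3))
})

test_that("enumeration is set-equal to the brute-force grid oracle", {
  set.seed(53)
  mzs <- runif(25, 80, 500)
  for (mz in mzs) {
    got <- enumerate_candidates(mz, "[M-H]-", element_limits("negative_pm"),
                                3)$formula
    want <- oracle_enumerate(mz, "[M-H]-", 3, cl_max = 0)
    expect_setequal(vapply(got, canonical_counts, character(1),
                           USE.NAMES = FALSE), want)
  }
  # surface-water mode brings chlorine in
  for (mz in mzs[1:8]) {
    got <- enumerate_candidates(mz, "[M-H]-",
                                element_limits("negative_water"), 3)$formula
    want <- oracle_enumerate(mz, "[M-H]-", 3, cl_max = 3)
    expect_setequal(vapply(got, canonical_counts, character(1),
                           USE.NAMES = FALSE), want)
  }
})

test_that("candidate sets are monotone in tolerance and element caps", {
  mz <- 311.1687  # [M-H]- of C17H28O3S
  lim <- element_limits("negative_pm")
  prev <- character(0)
  for (tol in c(0.5, 1, 3, 6)) {
    cur <- enumerate_candidates(mz, "[M-H]-", lim, tol)$formula
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # stricter limits give a subset
  strict <- element_limits("negative_pm", n_max = 0, s_max = 0)
  loose <- enumerate_candidates(mz, "[M-H]-", lim, 3)$formula
  tight <- enumerate_candidates(mz, "[M-H]-", strict, 3)$formula
  expect_true(all(tight %in% loose))
  # vanishing tolerance keeps at most the exact-mass formula
  exact <- enumerate_candidates(ion_mz(parse_formula("C17H28O3S"), "[M-H]-"),
                                "[M-H]-", lim, 0.01)$formula
  expect_true(length(exact) <= 1)
  expect_true(all(exact == "C17H28O3S"))
})

test_that("isotope verification applies the relative tolerance", {
  f <- parse_formula("C16H26O3S")
  th <- isotope_pattern(f, "[M-H]-")$rel
  exact <- check_isotopes(f, "[M-H]-", th[2:3])
  expect_true(exact$pass)
  expect_equal(exact$dev_a1, 0, tolerance = 1e-12)
  over <- check_isotopes(f, "[M-H]-", c(th[2] * 1.31, th[3]))
  expect_false(over$pass)
  within <- check_isotopes(f, "[M-H]-", th[2:3] * 1.10)
  expect_true(within$pass)
  # missing A+1 fails only when it should have been observable
  expect_false(check_isotopes(f, "[M-H]-", c(0, 0),
                              a_intensity = 1e6, floor = 3e4)$pass)
  expect_true(check_isotopes(f, "[M-H]-", c(0, 0),
                             a_intensity = 1e5, floor = 3e4)$pass)
})

test_that("erroneous-formula rules reject and log with one rule each", {
  res <- filter_erroneous(c("C7H8O2", "C2H9O", "C2H2O7", "C10H11NO"))
  expect_true("C7H8O2" %in% res$retained$formula)
  expect_true("C2H9O" %in% res$rejected$formula)
  expect_true("C2H2O7" %in% res$rejected$formula)
  # non-integer DBE (odd H for no N)
  expect_true("C10H11NO" %in% res$retained$formula)  # DBE 6, fine
  odd <- filter_erroneous("C10H11O")
  expect_equal(odd$rejected$rule, "non_integer_dbe")
  # conservation: retained + rejected = input, one rule per rejection
  expect_equal(nrow(res$retained) + nrow(res$rejected), 4)
  expect_true(all(nchar(res$rejected$rule) > 0))
  # empty rule set is the identity
  ident <- filter_erroneous(c("C2H9O", "C7H8O2"), rules = list())
  expect_equal(nrow(ident$retained), 2)
})

test_that("assignment recovers random legal formulas from their ion m/z", {
  set.seed(61)
  n <- 40
  ok_clean <- 0; ok_jitter <- 0
  for (i in 1:n) {
    f <- random_legal_formula()
    mz <- ion_mz(f, "[M-H]-")
    th <- isotope_pattern(f, "[M-H]-")$rel
    a <- assign_feature(mz, "[M-H]-", iso_obs = th[2:3] * runif(2, 0.95, 1.05),
                        intensity = 1e6)
    if (!is.na(a$formula) && a$formula == format_formula(f)) {
      ok_clean <- ok_clean + 1
    }
    jit <- mz * (1 + runif(1, -2e-6, 2e-6))
    aj <- assign_feature(jit, "[M-H]-", iso_obs = th[2:3] * runif(2, 0.9, 1.1),
                         intensity = 1e6)
    if (!is.na(aj$formula) && aj$formula == format_formula(f)) {
      ok_jitter <- ok_jitter + 1
    }
  }
  expect_gte(ok_clean / n, 0.99)
  expect_gte(ok_jitter / n, 0.95)
})

test_that("assignment statuses cover unassigned and ambiguous contracts", {
  # a window verified empty against the oracle
  mz_empty <- 72.60
  expect_equal(length(oracle_enumerate(mz_empty, "[M-H]-", 3)), 0)
  a <- assign_feature(mz_empty, "[M-H]-")
  expect_identical(a$status, "unassigned")
  expect_true(is.na(a$formula))
  # assigned ppm error strictly below tolerance
  f <- parse_formula("C16H26O3S")
  b <- assign_feature(ion_mz(f, "[M-H]-"), "[M-H]-")
  expect_identical(b$status, "assigned")
  expect_lt(abs(b$ppm_error), 3)
  # two survivors within 1 ppm are reported as ambiguous, both recorded
  mz_amb <- NULL
  set.seed(67)
  for (i in 1:200) {
    mz <- runif(1, 250, 500)
    cand <- enumerate_candidates(mz, "[M-H]-", tol_ppm = 3)
    surv <- filter_erroneous(cand)$retained
    if (nrow(surv) >= 2 && abs(surv$ppm[2] - surv$ppm[1]) <= 1) {
      mz_amb <- mz; break
    }
  }
  expect_false(is.null(mz_amb))
  amb <- assign_feature(mz_amb, "[M-H]-")
  expect_identical(amb$status, "ambiguous")
  expect_gt(nchar(amb$alternatives), 0)
})
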