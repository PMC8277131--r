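#' Element limits for formula enumeration
#'
#' Per-element count bounds for candidate enumeration. The defaults
#' encode the screening configuration: C, H, O unconstrained (capped
#' operationally by the target mass), N <= 5, S <= 2; Cl <= 3 only in
#' surface-water mode; in positive mode up to 2 Na and 1 K atoms may be
#' allowed in the formula itself, but because in-formula metals cause
#' pathological candidate growth they are off by default and Na/K are
#' normally handled as adduct species instead.
#'
#' @param mode \code{"negative_pm"} (particulate matter, negative),
#'   \code{"negative_water"} (surface water, allows Cl) or
#'   \code{"positive"}
#' @param allow_metals allow in-formula Na/K in positive mode
#' @param n_max,s_max,cl_max heteroatom caps
#' @return an \code{nts_limits} object with \code{max} and \code{min}
#'   named vectors
#' @export
element_limits <- function(mode = c("negative_pm", "negative_water",
                                    "positive"),
                           allow_metals = FALSE,
                           n_max = 5, s_max = 2, cl_max = 3) {
  mode <- match.arg(mode)
  mx <- c(C = Inf, H = Inf, N = n_max, O = Inf, S = s_max,
          Cl = 0, Na = 0, K = 0, P = 0)
  if (mode == "negative_water") mx[["Cl"]] <- cl_max
  if (mode == "positive" && allow_metals) {
    mx[["Na"]] <- 2; mx[["K"]] <- 1
  }
  structure(list(max = mx, min = stats::setNames(numeric(9), names(mx)),
                 mode = mode),
            class = "nts_limits")
}

#' Enumerate candidate molecular formulas for an ion m/z
#'
#' Exhaustively lists the neutral formulas whose theoretical ion m/z for
#' the given species lies within \code{+/- tol_ppm} (strict) of the
#' measured m/z, honoring the element limits. Enumeration runs over the
#' heteroatoms (Cl, S, N, Na, K, O) with a closed-form solve for the C/H
#' pair; the "unlimited" C, H, O counts are capped by the target mass
#' (C <= mass/12, O <= mass/15.99, H <= 2C + N + 2), which cannot
#' exclude any formula inside the tolerance.
#'
#' @param mz measured ion m/z
#' @param sp ion species (label or \code{nts_ion})
#' @param limits an \code{nts_limits}
#' @param tol_ppm mass tolerance in ppm (exclusive bound)
#' @return data.frame sorted by |ppm|: \code{formula, mz_theoretical,
#'   ppm} plus element-count columns; zero rows when no formula fits
#' @export
enumerate_candidates <- function(mz, sp, limits = element_limits(),
                                 tol_ppm = 3) {
  stopifnot(mz > 0, tol_ppm > 0)
  sp <- get_ion(sp)
  m_target <- (mz - sp$delta) / sp$n_m     # neutral monoisotopic mass
  tol_da <- mz * tol_ppm * 1e-6 / sp$n_m   # tolerance on the neutral mass
  mm <- .nts_monoiso
  mx <- limits$max
  cap <- function(el, hard) min(mx[[el]], hard)
  out <- list()
  for (ncl in 0:cap("Cl", floor((m_target + tol_da) / mm[["Cl"]])))
    for (ns in 0:cap("S", floor((m_target + tol_da) / mm[["S"]])))
      for (nn in 0:cap("N", floor((m_target + tol_da) / mm[["N"]])))
        for (nna in 0:cap("Na", floor((m_target + tol_da) / mm[["Na"]])))
          for (nk in 0:cap("K", floor((m_target + tol_da) / mm[["K"]]))) {
            het <- ncl * mm[["Cl"]] + ns * mm[["S"]] + nn * mm[["N"]] +
              nna * mm[["Na"]] + nk * mm[["K"]]
            if (het > m_target + tol_da) next
            o_hard <- floor((m_target + tol_da - het) / mm[["O"]])
            for (no in 0:cap("O", o_hard)) {
              rem <- m_target - het - no * mm[["O"]]
              nc_max <- floor((rem + tol_da) / 12)
              if (nc_max < 1) next
              for (nc in 1:nc_max) {
                h_real <- (rem - 12 * nc) / mm[["H"]]
                nh <- round(h_real)
                if (nh < 0 || nh > 2 * nc + nn + 2) next
                mass <- het + no * mm[["O"]] + 12 * nc + nh * mm[["H"]]
                mz_th <- sp$n_m * mass + sp$delta
                ppm <- (mz_th - mz) / mz * 1e6
                if (abs(ppm) >= tol_ppm) next
                f <- formula_of(C = nc, H = nh, N = nn, O = no, S = ns,
                                Cl = ncl, Na = nna, K = nk)
                out[[length(out) + 1]] <- data.frame(
                  formula = format_formula(f), mz_theoretical = mz_th,
                  ppm = ppm, C = nc, H = nh, N = nn, O = no, S = ns,
                  Cl = ncl, Na = nna, K = nk, stringsAsFactors = FALSE)
              }
            }
          }
  if (!length(out)) {
    return(data.frame(formula = character(0), mz_theoretical = numeric(0),
                      ppm = numeric(0), C = integer(0), H = integer(0),
                      N = integer(0), O = integer(0), S = integer(0),
                      Cl = integer(0), Na = integer(0), K = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(abs(res$ppm), res$formula), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Verify an observed isotope pattern against a candidate formula
#'
#' Each observed isotopologue's relative intensity (A normalized to 1)
#' must be within \code{+/- tol} (relative) of the theoretical pattern.
#' A missing A+1/A+2 fails the check only when the theoretical
#' isotopologue intensity (scaled by the observed A intensity) would have
#' been above the detection floor, i.e. observable.
#'
#' @param candidate neutral \code{nts_formula}
#' @param sp ion species
#' @param observed numeric: observed relative intensities
#'   \code{c(a1 = ..., a2 = ...)}; 0 or NA means not observed
#' @param tol relative tolerance (0.30 = +/-30 percent)
#' @param a_intensity absolute intensity of the A peak (for the
#'   observability floor); \code{NULL} disables the floor logic and
#'   treats missing isotopologues as unobservable
#' @param floor detection floor in absolute intensity units
#' @return list: \code{pass}, \code{dev_a1}, \code{dev_a2} (relative
#'   deviations, NA when unobserved and unobservable)
#' @export
check_isotopes <- function(candidate, sp, observed, tol = 0.30,
                           a_intensity = NULL, floor = 3e4) {
  th <- isotope_pattern(candidate, sp)$rel
  obs <- c(a1 = unname(observed[1]), a2 = unname(observed[2]))
  obs[is.na(obs)] <- 0
  devs <- c(a1 = NA_real_, a2 = NA_real_)
  pass <- TRUE
  for (k in 1:2) {
    th_k <- th[k + 1]
    if (obs[k] > 0) {
      if (th_k <= 0) { pass <- FALSE; devs[k] <- Inf; next }
      devs[k] <- obs[k] / th_k - 1
      if (abs(devs[k]) > tol) pass <- FALSE
    } else if (!is.null(a_intensity) && th_k * a_intensity >= floor) {
      pass <- FALSE  # should have been observable but was not seen
      devs[k] <- -1
    }
  }
  list(pass = pass, dev_a1 = devs[["a1"]], dev_a2 = devs[["a2"]])
}

#' Remove erroneous candidate formulas
#'
#' Chemistry-plausibility rules applied to candidate neutral formulas:
#' integer DBE (even-electron neutral), DBE >= 0, H/C within bounds, and
#' O/C below a cap. Each rejection records exactly one rule name (the
#' first failing rule in the order listed).
#'
#' @param candidates a candidate data.frame from
#'   \code{\link{enumerate_candidates}} or a character vector of
#'   formulas
#' @param rules list of bounds: \code{hc} (length-2 range), \code{oc_max},
#'   \code{require_integer_dbe}, \code{dbe_min}; an empty list disables
#'   all rules
#' @return list with \code{retained} and \code{rejected} (the latter with
#'   a \code{rule} column)
#' @export
filter_erroneous <- function(candidates,
                             rules = list(require_integer_dbe = TRUE,
                                          dbe_min = 0,
                                          hc = c(0.2, 3.1),
                                          oc_max = 3)) {
  if (is.character(candidates)) {
    candidates <- data.frame(formula = candidates, stringsAsFactors = FALSE)
  }
  if (!nrow(candidates)) {
    candidates$rule <- character(0)
    return(list(retained = candidates[, setdiff(names(candidates), "rule"),
                                      drop = FALSE],
                rejected = candidates))
  }
  rule <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    f <- parse_formula(candidates$formula[i])
    d <- dbe(f)
    hc <- if (f[["C"]] > 0) f[["H"]] / f[["C"]] else Inf
    oc <- if (f[["C"]] > 0) f[["O"]] / f[["C"]] else Inf
    rule[i] <- if (isTRUE(rules$require_integer_dbe) && d != round(d)) {
      "non_integer_dbe"
    } else if (!is.null(rules$dbe_min) && d < rules$dbe_min) {
      "negative_dbe"
    } else if (!is.null(rules$hc) && (hc < rules$hc[1] || hc > rules$hc[2])) {
      "hc_range"
    } else if (!is.null(rules$oc_max) && oc > rules$oc_max) {
      "oc_range"
    } else NA_character_
  }
  rejected <- candidates[!is.na(rule), , drop = FALSE]
  rejected$rule <- rule[!is.na(rule)]
  list(retained = candidates[is.na(rule), , drop = FALSE],
       rejected = rejected)
}

#' Assign a molecular formula to a feature
#'
#' Runs enumerate -> erroneous-filter -> isotope-check for each candidate
#' ion species of the feature and picks the lowest-|ppm| survivor.
#' Status is \code{"ambiguous"} when a second survivor lies within 1 ppm
#' of the best (both are reported), \code{"unassigned"} when nothing
#' survives, and \code{"rejected_erroneous"} when candidates existed but
#' all fell to the plausibility or isotope rules.
#'
#' @param mz measured feature m/z
#' @param species character vector of ion species labels to try, in
#'   preference order (a grouped component has one; an ungrouped feature
#'   in independent mode may carry several hypotheses)
#' @param iso_obs observed relative isotopologue intensities
#'   \code{c(a1, a2)} or \code{NULL} to skip the isotope check
#' @param intensity absolute A intensity (observability floor logic)
#' @param limits an \code{nts_limits}
#' @param tol_ppm mass tolerance (ppm, exclusive)
#' @param iso_tol isotope-pattern relative tolerance
#' @param rules erroneous-formula rules (see
#'   \code{\link{filter_erroneous}})
#' @param floor isotopologue detection floor
#' @return one-row data.frame: \code{mz, adduct, formula, ppm_error, dbe,
#'   status, n_candidates, isotope_dev_a1, isotope_dev_a2, alternatives}
#' @export
assign_feature <- function(mz, species, iso_obs = NULL, intensity = NULL,
                           limits = element_limits(), tol_ppm = 3,
                           iso_tol = 0.30,
                           rules = list(require_integer_dbe = TRUE,
                                        dbe_min = 0, hc = c(0.2, 3.1),
                                        oc_max = 3),
                           floor = 3e4) {
  best <- NULL
  n_cand_total <- 0L
  any_candidates <- FALSE
  for (lab in species) {
    cand <- enumerate_candidates(mz, lab, limits, tol_ppm)
    n_cand_total <- n_cand_total + nrow(cand)
    if (!nrow(cand)) next
    any_candidates <- TRUE
    surv <- filter_erroneous(cand, rules)$retained
    if (!nrow(surv)) next
    keep <- logical(nrow(surv))
    dev1 <- dev2 <- rep(NA_real_, nrow(surv))
    for (i in seq_len(nrow(surv))) {
      if (is.null(iso_obs)) { keep[i] <- TRUE; next }
      chk <- check_isotopes(parse_formula(surv$formula[i]), lab, iso_obs,
                            tol = iso_tol, a_intensity = intensity,
                            floor = floor)
      keep[i] <- chk$pass
      dev1[i] <- chk$dev_a1; dev2[i] <- chk$dev_a2
    }
    surv <- surv[keep, , drop = FALSE]
    dev1 <- dev1[keep]; dev2 <- dev2[keep]
    if (!nrow(surv)) next
    cand_best <- list(adduct = lab, formula = surv$formula[1],
                      ppm = surv$ppm[1], dev_a1 = dev1[1], dev_a2 = dev2[1],
                      others = if (nrow(surv) > 1) {
                        surv$formula[-1][abs(surv$ppm[-1] - surv$ppm[1]) <= 1]
                      } else character(0))
    if (is.null(best) || abs(cand_best$ppm) < abs(best$ppm)) best <- cand_best
  }
  if (is.null(best)) {
    status <- if (any_candidates) "rejected_erroneous" else "unassigned"
    return(data.frame(mz = mz, adduct = NA_character_,
                      formula = NA_character_, ppm_error = NA_real_,
                      dbe = NA_real_, status = status,
                      n_candidates = n_cand_total,
                      isotope_dev_a1 = NA_real_, isotope_dev_a2 = NA_real_,
                      alternatives = "", stringsAsFactors = FALSE))
  }
  status <- if (length(best$others)) "ambiguous" else "assigned"
  data.frame(mz = mz, adduct = best$adduct, formula = best$formula,
             ppm_error = best$ppm, dbe = dbe(parse_formula(best$formula)),
             status = status, n_candidates = n_cand_total,
             isotope_dev_a1 = best$dev_a1, isotope_dev_a2 = best$dev_a2,
             alternatives = paste(best$others, collapse = ";"),
             stringsAsFactors = FALSE)
}
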