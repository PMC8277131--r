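# evaluate code under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a simulated analyte
#'
#' Describes one compound in a synthetic run: neutral formula,
#' chromatographic elution (Gaussian in RT), apex intensity and how its
#' signal splits across ion species. The generator places one centroid
#' per isotopologue per scan at the theoretical ion m/z with ppm-scale
#' jitter, emulating centroided Orbitrap-style data.
#'
#' @param formula neutral formula (string or \code{nts_formula})
#' @param rt apex retention time (min)
#' @param width chromatographic peak sigma (min)
#' @param intensity apex intensity of the full signal
#' @param adducts named numeric vector of signal fractions per ion
#'   species (must sum to 1)
#' @param name analyte label
#' @param ms2 optional data.frame of MS2 fragments (\code{mz},
#'   \code{intensity}) recorded at the apex
#' @return an \code{nts_analyte}
#' @export
analyte_spec <- function(formula, rt, width = 0.05, intensity = 1e6,
                         adducts = c("[M-H]-" = 1), name = NULL,
                         ms2 = NULL) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(intensity > 0, width > 0,
            abs(sum(adducts) - 1) < 1e-9)
  pol <- unique(vapply(names(adducts),
                       function(l) get_ion(l)$polarity, character(1)))
  stopifnot(length(pol) == 1)
  if (is.null(name)) name <- format_formula(formula)
  structure(list(formula = formula, rt = rt, width = width,
                 intensity = intensity, adducts = adducts,
                 polarity = pol, name = name, ms2 = ms2),
            class = "nts_analyte")
}

#' Noise model for synthetic runs
#'
#' @param background_density expected chemical-background centroids per
#'   scan per Th (uniform m/z, exponential intensity)
#' @param background_intensity mean intensity of background centroids
#' @param ppm_jitter standard deviation of the per-centroid mass error
#'   (ppm)
#' @param intensity_cv multiplicative intensity noise (coefficient of
#'   variation) on analyte centroids
#' @param seed RNG seed; fixes the generated run bit-exactly
#' @return an \code{nts_noise}
#' @export
noise_spec <- function(background_density = 0.2,
                       background_intensity = 2e3,
                       ppm_jitter = 1, intensity_cv = 0.02, seed = 1) {
  stopifnot(background_density >= 0, background_intensity >= 0,
            ppm_jitter >= 0, intensity_cv >= 0)
  structure(list(background_density = background_density,
                 background_intensity = background_intensity,
                 ppm_jitter = ppm_jitter, intensity_cv = intensity_cv,
                 seed = seed),
            class = "nts_noise")
}

#' Generate a synthetic centroided LC-MS run with ground truth
#'
#' Each analyte contributes, per ion species, a Gaussian-in-RT centroid
#' series at the theoretical ion m/z, with A+1/A+2 isotopologue
#' centroids scaled by the theoretical isotope pattern, seeded ppm mass
#' jitter and multiplicative intensity noise. Chemical background
#' (uniform m/z, exponential intensity) and optional constant-m/z
#' interference ridges are added. The ground truth lists every injected
#' ion with its m/z, RT, apex intensity and analytic Gaussian area;
#' overlapping same-m/z injections are flagged.
#'
#' @param analytes list of \code{\link{analyte_spec}}
#' @param noise an \code{\link{noise_spec}}
#' @param rt_range RT span in minutes
#' @param scan_hz scan rate in scans per second
#' @param mz_range m/z span for background generation
#' @param sample,role run labels (see \code{\link{new_run}})
#' @param ridges optional data.frame (\code{mz, mean, sd}): per-scan
#'   interference centroids at fixed m/z with Gaussian intensity,
#'   used to emulate unresolved co-eluting interferences
#' @return list with \code{run} (an \code{nts_run}), \code{truth}
#'   (data.frame: name, formula, adduct, mz, rt, apex, area, overlap)
#'   and \code{ms2} (named list of \code{nts_ms2} for analytes carrying
#'   fragments)
#' @export
make_run <- function(analytes, noise = noise_spec(), rt_range = c(0, 10),
                     scan_hz = 1, mz_range = c(50, 500),
                     sample = "sample", role = "sample", ridges = NULL) {
  pol <- unique(vapply(analytes, function(a) a$polarity, character(1)))
  if (length(pol) > 1) stop("analytes span both polarities")
  if (length(pol) == 0) pol <- "negative"
  .with_seed(noise$seed, {
    rt <- seq(rt_range[1], rt_range[2], by = 1 / (60 * scan_hz))
    nscan <- length(rt)
    cen <- list()
    truth <- list()
    ms2 <- list()
    for (a in analytes) {
      for (lab in names(a$adducts)) {
        frac <- a$adducts[[lab]]
        if (frac <= 0) next
        pat <- isotope_pattern(a$formula, lab)
        apex <- a$intensity * frac
        for (k in seq_len(nrow(pat))) {
          rel <- pat$rel[k]
          if (rel < 1e-4) next
          prof <- apex * rel * exp(-(rt - a$rt)^2 / (2 * a$width^2))
          keep <- which(prof >= 1)
          if (!length(keep)) next
          it <- prof[keep]
          if (noise$intensity_cv > 0) {
            it <- it * exp(stats::rnorm(length(it), 0,
                                        noise$intensity_cv))
          }
          mz <- pat$mz[k] *
            (1 + stats::rnorm(length(keep), 0, noise$ppm_jitter * 1e-6))
          cen[[length(cen) + 1]] <-
            data.frame(scan = keep, mz = mz, intensity = it)
        }
        truth[[length(truth) + 1]] <- data.frame(
          name = a$name, formula = format_formula(a$formula),
          adduct = lab, mz = pat$mz[1], rt = a$rt, apex = apex,
          area = apex * a$width * sqrt(2 * pi),
          stringsAsFactors = FALSE)
      }
      if (!is.null(a$ms2)) {
        pref_lab <- names(a$adducts)[which.max(a$adducts)]
        ms2[[a$name]] <- ms2_spectrum(a$ms2,
                                      precursor_mz = ion_mz(a$formula,
                                                            pref_lab),
                                      species = pref_lab, rt = a$rt)
      }
    }
    if (noise$background_density > 0) {
      span <- diff(mz_range)
      n_bg <- stats::rpois(nscan, noise$background_density * span)
      tot <- sum(n_bg)
      if (tot > 0) {
        cen[[length(cen) + 1]] <- data.frame(
          scan = rep(seq_len(nscan), n_bg),
          mz = stats::runif(tot, mz_range[1], mz_range[2]),
          intensity = stats::rexp(tot, 1 / noise$background_intensity))
      }
    }
    if (!is.null(ridges)) {
      for (i in seq_len(nrow(ridges))) {
        it <- pmax(stats::rnorm(nscan, ridges$mean[i], ridges$sd[i]), 0)
        mz <- ridges$mz[i] *
          (1 + stats::rnorm(nscan, 0, noise$ppm_jitter * 1e-6))
        cen[[length(cen) + 1]] <-
          data.frame(scan = seq_len(nscan), mz = mz, intensity = it)
      }
    }
    centroids <- if (length(cen)) do.call(rbind, cen) else
      data.frame(scan = integer(0), mz = numeric(0),
                 intensity = numeric(0))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(name = character(0), formula = character(0),
                 adduct = character(0), mz = numeric(0), rt = numeric(0),
                 apex = numeric(0), area = numeric(0),
                 stringsAsFactors = FALSE)
    if (nrow(truth)) {
      truth$overlap <- vapply(seq_len(nrow(truth)), function(i) {
        any(abs(truth$mz[-i] - truth$mz[i]) <=
              truth$mz[i] * 5e-6 &
              abs(truth$rt[-i] - truth$rt[i]) <= 0.2)
      }, logical(1))
    }
    run <- new_run(rt, centroids, polarity = pol, sample = sample,
                   role = role)
    list(run = run, truth = truth, ms2 = ms2)
  })
}

#' Generate a blank run sharing artifact analytes with samples
#'
#' A blank contains only the shared artifact analytes plus noise, for
#' exercising blank subtraction.
#'
#' @param artifacts list of \code{\link{analyte_spec}} present in the
#'   blank
#' @param noise an \code{\link{noise_spec}}
#' @param role \code{"solvent_blank"} or \code{"procedural_blank"}
#' @param ... passed to \code{\link{make_run}}
#' @return as \code{\link{make_run}}
#' @export
make_blank <- function(artifacts, noise = noise_spec(),
                       role = "solvent_blank", ...) {
  make_run(artifacts, noise = noise, role = role,
           sample = role, ...)
}

#' Generate a calibration series of runs
#'
#' Triplicate (by default) runs per concentration level with apex
#' intensity proportional to concentration times the response factor,
#' under seeded multiplicative noise. Low concentrations whose apex
#' falls below the detection threshold reproduce realistic
#' low-concentration dropouts.
#'
#' @param analyte an \code{\link{analyte_spec}} (its \code{intensity}
#'   field is overridden per level)
#' @param concentrations numeric vector of at least 5 levels
#' @param response_factor apex intensity per concentration unit
#' @param noise an \code{\link{noise_spec}}; each run gets a distinct
#'   seed derived from it
#' @param replicates runs per level
#' @param ... passed to \code{\link{make_run}}
#' @return list of records, each with \code{concentration},
#'   \code{replicate}, \code{run}, \code{truth}
#' @export
make_calibration_series <- function(analyte, concentrations,
                                    response_factor, noise = noise_spec(),
                                    replicates = 3, ...) {
  stopifnot(length(unique(concentrations)) >= 5)
  out <- list()
  i <- 0L
  for (conc in concentrations) {
    for (rep in seq_len(replicates)) {
      i <- i + 1L
      a <- analyte
      a$intensity <- conc * response_factor
      n <- noise
      n$seed <- noise$seed + i
      r <- make_run(list(a), noise = n,
                    sample = sprintf("cal_%g_r%d", conc, rep), ...)
      out[[i]] <- list(concentration = conc, replicate = rep,
                       run = r$run, truth = r$truth)
    }
  }
  out
}

#' Positive-mode fixture of sodium-only analytes
#'
#' Emulates compounds observed exclusively as \code{[M+Na]+} (as
#' levoglucosan-like sugars and hydroxy acids are), plus optionally some
#' ordinary protonated analytes. Used to demonstrate that
#' vendor-compatible adduct grouping cannot recognize sodium-only
#' compounds while independent grouping can.
#'
#' @param with_protonated also include two analytes carrying
#'   \code{[M+H]+} signal
#' @param seed RNG seed
#' @return as \code{\link{make_run}}, plus \code{na_only_names}
#' @export
sodium_only_fixture <- function(with_protonated = FALSE, seed = 42) {
  na_only <- list(
    analyte_spec("C6H10O5", rt = 1.5, intensity = 5e5,
                 adducts = c("[M+Na]+" = 1), name = "sugar_anhydride"),
    analyte_spec("C6H12O3", rt = 3.0, intensity = 4e5,
                 adducts = c("[M+Na]+" = 1), name = "hydroxy_acid_C6"),
    analyte_spec("C5H10O3", rt = 2.2, intensity = 6e5,
                 adducts = c("[M+Na]+" = 1), name = "hydroxy_acid_C5"),
    analyte_spec("C9H14O6", rt = 4.1, intensity = 3e5,
                 adducts = c("[M+Na]+" = 1), name = "triacetin_like"))
  analytes <- na_only
  if (with_protonated) {
    analytes <- c(analytes, list(
      analyte_spec("C7H7NO2", rt = 5.2, intensity = 8e5,
                   adducts = c("[M+H]+" = 0.7, "[M+Na]+" = 0.3),
                   name = "aminobenzoate"),
      analyte_spec("C10H14N2", rt = 6.0, intensity = 7e5,
                   adducts = c("[M+H]+" = 1), name = "nicotine_like")))
  }
  res <- make_run(analytes, noise = noise_spec(seed = seed),
                  rt_range = c(0, 8))
  res$na_only_names <- vapply(na_only, function(a) a$name, character(1))
  res
}

#' Interference fixture for the unit- vs accurate-mass mechanism
#'
#' One analyte inside the accurate-mass window plus a noisy constant
#' interference ridge elsewhere in the same unit-mass window. The ridge
#' inflates the unit-window baseline noise and depresses the unit-mode
#' S/N while leaving the accurate-mode S/N untouched.
#'
#' @param apex analyte apex intensity
#' @param ridge_mean,ridge_sd interference ridge intensity parameters
#' @param seed RNG seed
#' @return as \code{\link{make_run}}; the analyte is deprotonated
#'   methylcatechol-like C7H8O2 at m/z 123.0452
#' @export
interference_fixture <- function(apex = 5e4, ridge_mean = 2e4,
                                 ridge_sd = 8e3, seed = 7) {
  a <- analyte_spec("C7H8O2", rt = 5, width = 0.05, intensity = apex,
                    adducts = c("[M-H]-" = 1), name = "methylcatechol")
  make_run(list(a), noise = noise_spec(seed = seed,
                                       background_density = 0.05),
           rt_range = c(0, 10),
           ridges = data.frame(mz = 123.62, mean = ridge_mean,
                               sd = ridge_sd))
}
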