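#' LC-MS runs of centroided scans
#'
#' A run is a time-ordered sequence of centroided MS1 scans with a single
#' polarity. Centroids are held in one long-format table for fast window
#' queries.
#'
#' @param rt numeric vector of scan retention times (minutes),
#'   non-decreasing
#' @param centroids data.frame with columns \code{scan} (1-based index
#'   into \code{rt}), \code{mz}, \code{intensity}
#' @param polarity \code{"positive"} or \code{"negative"}
#' @param sample sample label
#' @param role \code{"sample"}, \code{"solvent_blank"} or
#'   \code{"procedural_blank"}
#' @return an \code{nts_run}
#' @export
new_run <- function(rt, centroids, polarity,
                    sample = "sample", role = "sample") {
  stopifnot(length(rt) >= 1, !is.unsorted(rt),
            polarity %in% c("positive", "negative"),
            role %in% c("sample", "solvent_blank", "procedural_blank"),
            all(c("scan", "mz", "intensity") %in% names(centroids)))
  if (nrow(centroids)) {
    stopifnot(all(centroids$scan >= 1), all(centroids$scan <= length(rt)),
              all(centroids$intensity >= 0))
    centroids <- centroids[order(centroids$scan, centroids$mz), , drop = FALSE]
    rownames(centroids) <- NULL
  }
  structure(list(rt = as.numeric(rt), centroids = centroids,
                 polarity = polarity, sample = sample, role = role),
            class = "nts_run")
}

#' @export
print.nts_run <- function(x, ...) {
  cat(sprintf("<run> %s (%s, %s): %d scans, %d centroids, RT %.2f-%.2f min\n",
              x$sample, x$role, x$polarity, length(x$rt),
              nrow(x$centroids), min(x$rt), max(x$rt)))
  invisible(x)
}

#' m/z extraction windows
#'
#' Unit-mass windows are integer-bounded and one Th wide
#' (\code{[floor(mz), floor(mz)+1)}); accurate-mass windows are narrow
#' intervals around a target. Both are half-open on the right.
#'
#' @param low,high window bounds in Th
#' @param mode \code{"unit"} or \code{"accurate"}
#' @return an \code{nts_window}
#' @export
mz_window <- function(low, high, mode = c("accurate", "unit")) {
  mode <- match.arg(mode)
  stopifnot(low < high)
  if (mode == "unit") {
    stopifnot(low == floor(low), high == low + 1)
  }
  structure(list(low = low, high = high, mode = mode), class = "nts_window")
}

#' Window for a target m/z in unit or accurate mode
#'
#' @param mz target m/z
#' @param mode \code{"unit"} gives \code{[floor(mz), floor(mz)+1)};
#'   \code{"accurate"} gives \code{mz * (1 +/- tol_ppm * 1e-6)}
#' @param tol_ppm accurate-mode half-width in ppm
#' @return an \code{nts_window}
#' @export
window_for <- function(mz, mode = c("accurate", "unit"), tol_ppm = 5) {
  mode <- match.arg(mode)
  if (mode == "unit") {
    mz_window(floor(mz), floor(mz) + 1, "unit")
  } else {
    mz_window(mz * (1 - tol_ppm * 1e-6), mz * (1 + tol_ppm * 1e-6), "accurate")
  }
}

#' Extracted ion chromatogram
#'
#' Per scan, the sum of centroid intensities with
#' \code{low <= mz < high}; zero where no centroid falls in the window.
#'
#' @param run an \code{nts_run}
#' @param w an \code{nts_window}
#' @return an \code{nts_eic}: list with \code{rt}, \code{intensity},
#'   \code{window}
#' @export
extract_eic <- function(run, w) {
  stopifnot(inherits(run, "nts_run"), inherits(w, "nts_window"))
  cen <- run$centroids
  sel <- cen$mz >= w$low & cen$mz < w$high
  intensity <- numeric(length(run$rt))
  if (any(sel)) {
    sums <- tapply(cen$intensity[sel], cen$scan[sel], sum)
    intensity[as.integer(names(sums))] <- as.numeric(sums)
  }
  structure(list(rt = run$rt, intensity = intensity, window = w),
            class = "nts_eic")
}

#' Robust baseline-noise estimate of an EIC
#'
#' Noise amplitude is 1.4826 x the median absolute deviation of the
#' intensities outside an optional exclusion interval (so a peak's own
#' region does not inflate its noise). Deterministic; scales with a
#' Gaussian baseline's sigma.
#'
#' @param eic an \code{nts_eic}
#' @param exclusion optional RT interval \code{c(lo, hi)} to exclude
#' @return noise amplitude (same units as intensity)
#' @export
estimate_noise <- function(eic, exclusion = NULL) {
  stopifnot(inherits(eic, "nts_eic"))
  x <- eic$intensity
  if (!is.null(exclusion)) {
    keep <- eic$rt < exclusion[1] | eic$rt > exclusion[2]
    x <- x[keep]
  }
  if (length(x) < 10) stop("fewer than 10 baseline scans for noise estimate")
  stats::mad(x, constant = 1.4826)
}

#' Trapezoidal area of an EIC between RT bounds
#'
#' @param eic an \code{nts_eic}
#' @param bounds RT interval \code{c(lo, hi)} in minutes
#' @return area in intensity x minutes
#' @export
integrate_peak <- function(eic, bounds) {
  stopifnot(inherits(eic, "nts_eic"), length(bounds) == 2)
  if (bounds[1] >= bounds[2]) stop("inverted integration bounds")
  eps <- 1e-9 * max(abs(bounds), 1)
  sel <- eic$rt >= bounds[1] - eps & eic$rt <= bounds[2] + eps
  rt <- eic$rt[sel]; y <- eic$intensity[sel]
  if (length(rt) < 2) return(0)
  sum(diff(rt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# local maxima indices (plateaus report their first scan)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x > c(-Inf, x[-n]) & x >= c(x[-1], -Inf))
}

#' Detect chromatographic peaks in an EIC
#'
#' A peak is a local maximum whose apex intensity reaches
#' \code{min_intensity}, whose apex-to-noise ratio exceeds \code{min_sn},
#' and which stays above the counting level for at least \code{min_scans}
#' consecutive scans. The counting level is
#' \code{max(baseline + noise, 0.5\% of apex)}; the baseline is the EIC
#' median. Peak bounds are the nearest flanking local minimum or
#' baseline crossing, whichever is closer to the apex. Each peak's noise
#' is re-estimated with its own RT region excluded.
#'
#' @param eic an \code{nts_eic}
#' @param min_sn minimum signal-to-noise ratio (exclusive)
#' @param min_intensity minimum apex intensity
#' @param min_scans minimum consecutive scans above the counting level
#' @return data.frame, one row per peak: \code{apex_rt, rt_lo, rt_hi,
#'   intensity, area, sn, n_scans, apex_scan}; zero rows when nothing
#'   qualifies
#' @export
detect_peaks <- function(eic, min_sn = 3, min_intensity = 3e4,
                         min_scans = 3) {
  stopifnot(inherits(eic, "nts_eic"))
  empty <- data.frame(apex_rt = numeric(0), rt_lo = numeric(0),
                      rt_hi = numeric(0), intensity = numeric(0),
                      area = numeric(0), sn = numeric(0),
                      n_scans = integer(0), apex_scan = integer(0))
  x <- eic$intensity
  n <- length(x)
  if (n < 3 || all(x == 0)) return(empty)
  baseline <- stats::median(x)
  noise_global <- stats::mad(x, constant = 1.4826)
  cross <- baseline + noise_global
  apexes <- .local_maxima(x)
  apexes <- apexes[x[apexes] >= min_intensity]
  if (!length(apexes)) return(empty)
  apexes <- apexes[order(-x[apexes])]
  claimed <- logical(n)
  out <- list()
  for (a in apexes) {
    if (claimed[a]) next
    # walk out to nearest local minimum or baseline crossing
    lo <- a
    while (lo > 1 && x[lo - 1] <= x[lo] && x[lo] > cross) lo <- lo - 1
    hi <- a
    while (hi < n && x[hi + 1] <= x[hi] && x[hi] > cross) hi <- hi + 1
    level <- max(cross, 0.005 * x[a])
    above <- x >= level
    j <- a
    while (j > lo && above[j - 1]) j <- j - 1
    k <- a
    while (k < hi && above[k + 1]) k <- k + 1
    n_scans <- k - j + 1
    claimed[lo:hi] <- TRUE
    # re-estimate noise with the peak region excluded
    pad <- (eic$rt[hi] - eic$rt[lo])
    excl <- c(eic$rt[lo] - pad, eic$rt[hi] + pad)
    keep <- eic$rt < excl[1] | eic$rt > excl[2]
    noise <- if (sum(keep) >= 10) {
      stats::mad(x[keep], constant = 1.4826)
    } else noise_global
    sn <- if (noise == 0) Inf else x[a] / noise
    if (sn <= min_sn || n_scans < min_scans) next
    area <- integrate_peak(eic, c(eic$rt[lo], eic$rt[hi]))
    out[[length(out) + 1]] <- data.frame(
      apex_rt = eic$rt[a], rt_lo = eic$rt[lo], rt_hi = eic$rt[hi],
      intensity = x[a], area = area, sn = sn,
      n_scans = as.integer(n_scans), apex_scan = as.integer(a))
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$apex_rt), , drop = FALSE]
}

#' S/N of a target species in unit- or accurate-mass mode
#'
#' Builds the unit window \code{[floor(mz), floor(mz)+1)} or the accurate
#' window \code{mz +/- tol_ppm}, takes the EIC apex, and divides by the
#' baseline noise estimated with the apex region excluded. A noise-free
#' EIC reports \code{Inf}. This is the mechanism behind the unit- vs
#' accurate-mass resolution comparison: interferences inside the unit
#' window inflate the noise and depress the unit-mode S/N.
#'
#' @param run an \code{nts_run}
#' @param mz target m/z
#' @param mode \code{"unit"} or \code{"accurate"}
#' @param tol_ppm accurate-window half width (ppm)
#' @param apex_halfwidth RT half-width (min) excluded around the apex
#'   when estimating noise
#' @return list with \code{sn}, \code{apex_rt}, \code{apex_intensity},
#'   \code{noise}, \code{window}
#' @export
sn_for_species <- function(run, mz, mode = c("accurate", "unit"),
                           tol_ppm = 5, apex_halfwidth = 0.25) {
  mode <- match.arg(mode)
  w <- window_for(mz, mode, tol_ppm)
  eic <- extract_eic(run, w)
  if (all(eic$intensity == 0)) stop("no signal in window")
  a <- which.max(eic$intensity)
  excl <- c(eic$rt[a] - apex_halfwidth, eic$rt[a] + apex_halfwidth)
  noise <- estimate_noise(eic, exclusion = excl)
  sn <- if (noise == 0) Inf else eic$intensity[a] / noise
  list(sn = sn, apex_rt = eic$rt[a], apex_intensity = eic$intensity[a],
       noise = noise, window = w)
}

#' S/N improvement factor between two extraction modes
#'
#' @param sn_accurate,sn_unit the two S/N values
#' @return list with the raw ratio and the factor rounded to the nearest
#'   integer, as conventionally reported
#' @export
sn_improvement_factor <- function(sn_accurate, sn_unit) {
  stopifnot(sn_unit > 0)
  ratio <- sn_accurate / sn_unit
  list(ratio = ratio, factor = round(ratio))
}

# cluster a run's centroids into narrow m/z bins; returns a data.frame of
# bin summaries (used for feature detection and alignment anchors)
.mz_bins <- function(run, gap = 0.008, min_points = 3) {
  cen <- run$centroids
  if (!nrow(cen)) {
    return(data.frame(mz = numeric(0), mz_lo = numeric(0),
                      mz_hi = numeric(0), max_intensity = numeric(0),
                      n = integer(0)))
  }
  ord <- order(cen$mz)
  mz <- cen$mz[ord]; it <- cen$intensity[ord]
  brk <- c(0, which(diff(mz) > gap), length(mz))
  bins <- lapply(seq_len(length(brk) - 1), function(i) {
    idx <- (brk[i] + 1):brk[i + 1]
    if (length(idx) < min_points) return(NULL)
    data.frame(mz = sum(mz[idx] * it[idx]) / sum(it[idx]),
               mz_lo = mz[idx[1]], mz_hi = mz[idx[length(idx)]],
               max_intensity = max(it[idx]), n = length(idx))
  })
  out <- do.call(rbind, bins)
  if (is.null(out)) {
    out <- data.frame(mz = numeric(0), mz_lo = numeric(0),
                      mz_hi = numeric(0), max_intensity = numeric(0),
                      n = integer(0))
  }
  out
}

#' Detect all features in a run
#'
#' Non-targeted detection: centroids are clustered into narrow m/z bins,
#' an accurate-mass EIC is built for every bin whose maximum intensity
#' can reach the detection threshold, and \code{\link{detect_peaks}} is
#' applied. Isotopologue features (a weaker co-eluting peak one or two
#' isotope spacings above a stronger one) are removed and counted.
#' Observed A+1/A+2 relative intensities are measured at each feature's
#' apex scan in windows \code{mz + k*1.00336 +/- 0.015} (wide enough to
#' cover the 13C2 / 34S / 18O spread).
#'
#' @param run an \code{nts_run}
#' @param min_sn,min_intensity,min_scans peak-detection gates
#' @param iso_rt_tol RT tolerance (min) for isotopologue de-duplication
#' @return data.frame of features: \code{feature_id, mz, rt, rt_lo,
#'   rt_hi, intensity, area, sn, n_scans, iso_a1, iso_a2}, with attribute
#'   \code{n_isotope_removed}
#' @export
detect_features <- function(run, min_sn = 3, min_intensity = 3e4,
                            min_scans = 3, iso_rt_tol = 0.05) {
  stopifnot(inherits(run, "nts_run"))
  bins <- .mz_bins(run)
  bins <- bins[bins$max_intensity >= min_intensity, , drop = FALSE]
  feats <- list()
  for (i in seq_len(nrow(bins))) {
    w <- mz_window(bins$mz_lo[i] - 1e-4, bins$mz_hi[i] + 1e-4)
    eic <- extract_eic(run, w)
    pk <- detect_peaks(eic, min_sn, min_intensity, min_scans)
    if (!nrow(pk)) next
    pk$mz <- bins$mz[i]
    feats[[length(feats) + 1]] <- pk
  }
  empty <- data.frame(feature_id = character(0), mz = numeric(0),
                      rt = numeric(0), rt_lo = numeric(0),
                      rt_hi = numeric(0), intensity = numeric(0),
                      area = numeric(0), sn = numeric(0),
                      n_scans = integer(0), iso_a1 = numeric(0),
                      iso_a2 = numeric(0))
  if (!length(feats)) {
    attr(empty, "n_isotope_removed") <- 0L
    return(empty)
  }
  ft <- do.call(rbind, feats)
  names(ft)[names(ft) == "apex_rt"] <- "rt"
  # isotopologue de-duplication: drop weaker co-eluting +1/+2 features
  drop <- logical(nrow(ft))
  for (i in seq_len(nrow(ft))) {
    for (k in 1:2) {
      cand <- abs(ft$mz - (ft$mz[i] + k * 1.00336)) <= 0.02 &
        abs(ft$rt - ft$rt[i]) <= iso_rt_tol &
        ft$intensity < 0.6 * ft$intensity[i]
      drop[cand] <- TRUE
    }
  }
  n_iso <- sum(drop)
  ft <- ft[!drop, , drop = FALSE]
  # observed isotopologue intensities at the apex scan
  cen <- run$centroids
  iso_obs <- function(mz, scan, k) {
    sel <- cen$scan == scan &
      abs(cen$mz - (mz + k * 1.00336)) <= 0.015
    sum(cen$intensity[sel])
  }
  ft$iso_a1 <- vapply(seq_len(nrow(ft)), function(i)
    iso_obs(ft$mz[i], ft$apex_scan[i], 1) / ft$intensity[i], numeric(1))
  ft$iso_a2 <- vapply(seq_len(nrow(ft)), function(i)
    iso_obs(ft$mz[i], ft$apex_scan[i], 2) / ft$intensity[i], numeric(1))
  ft <- ft[order(ft$mz, ft$rt), , drop = FALSE]
  ft$feature_id <- sprintf("F%04d", seq_len(nrow(ft)))
  ft$apex_scan <- NULL
  rownames(ft) <- NULL
  ft <- ft[, c("feature_id", "mz", "rt", "rt_lo", "rt_hi", "intensity",
               "area", "sn", "n_scans", "iso_a1", "iso_a2")]
  attr(ft, "n_isotope_removed") <- n_iso
  ft
}

#' Align retention times across runs
#'
#' Fits a monotone piecewise-linear RT correction per run against a
#' reference run, from anchor features (intense m/z bins) matched by m/z
#' within \code{mz_tol_ppm} and RT within \code{rt_tol}. Monotonicity is
#' enforced by isotonic regression of reference RT on run RT. With no
#' usable anchors the warp falls back to identity with a warning.
#'
#' @param runs list of \code{nts_run}
#' @param reference index of the reference run
#' @param mz_tol_ppm anchor m/z matching tolerance
#' @param rt_tol anchor RT matching tolerance (min)
#' @param min_intensity minimum anchor intensity
#' @return list with \code{warps} (one function per run mapping run RT to
#'   reference RT) and \code{summary} (per-run anchor count and max
#'   absolute correction)
#' @export
align_runs <- function(runs, reference = 1, mz_tol_ppm = 10, rt_tol = 0.5,
                       min_intensity = 1e5) {
  stopifnot(length(runs) >= 1)
  anchors <- lapply(runs, function(r) {
    b <- .mz_bins(r)
    b <- b[b$max_intensity >= min_intensity, , drop = FALSE]
    b$rt <- vapply(seq_len(nrow(b)), function(i) {
      eic <- extract_eic(r, mz_window(b$mz_lo[i] - 1e-4, b$mz_hi[i] + 1e-4))
      r$rt[which.max(eic$intensity)]
    }, numeric(1))
    b
  })
  ref <- anchors[[reference]]
  warps <- vector("list", length(runs))
  summ <- data.frame(run = seq_along(runs), n_anchors = 0L,
                     max_correction = 0)
  for (i in seq_along(runs)) {
    if (i == reference) { warps[[i]] <- identity; next }
    a <- anchors[[i]]
    pairs <- list()
    for (j in seq_len(nrow(a))) {
      hit <- which(abs(ref$mz - a$mz[j]) <= ref$mz * mz_tol_ppm * 1e-6 &
                     abs(ref$rt - a$rt[j]) <= rt_tol)
      if (length(hit)) {
        hit <- hit[which.min(abs(ref$rt[hit] - a$rt[j]))]
        pairs[[length(pairs) + 1]] <- c(a$rt[j], ref$rt[hit])
      }
    }
    if (length(pairs) < 2) {
      warning("no alignment anchors for run ", i, "; identity warp used")
      warps[[i]] <- identity
      next
    }
    p <- do.call(rbind, pairs)
    p <- p[order(p[, 1]), , drop = FALSE]
    iso <- stats::isoreg(p[, 1], p[, 2])
    fx <- unique(cbind(iso$x, iso$yf))
    if (nrow(fx) < 2) { warps[[i]] <- identity; next }
    base <- stats::approxfun(fx[, 1], fx[, 2], rule = 2)
    lo <- fx[1, ]; hi <- fx[nrow(fx), ]
    warp <- local({
      base_f <- base; lo_ <- lo; hi_ <- hi
      function(rt) {
        y <- base_f(rt)
        # extend with the boundary offset so the warp stays monotone
        y[rt < lo_[1]] <- rt[rt < lo_[1]] + (lo_[2] - lo_[1])
        y[rt > hi_[1]] <- rt[rt > hi_[1]] + (hi_[2] - hi_[1])
        y
      }
    })
    warps[[i]] <- warp
    summ$n_anchors[i] <- nrow(p)
    summ$max_correction[i] <- max(abs(p[, 2] - p[, 1]))
  }
  list(warps = warps, summary = summ)
}

#' Apply an RT warp to a run
#'
#' @param run an \code{nts_run}
#' @param warp a function mapping run RT to reference RT
#' @return the run with corrected scan retention times
#' @export
apply_warp <- function(run, warp) {
  rt <- warp(run$rt)
  rt <- cummax(rt)  # guard against numerical non-monotonicity
  run$rt <- rt
  run
}
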