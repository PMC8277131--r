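#' Fit a linear calibration
#'
#' Ordinary least squares of mean peak area on concentration over
#' replicate measurements. The calibration protocol requires at least
#' five distinct concentrations with three replicates each; per-level
#' relative standard deviations and the valid concentration range are
#' stored with the fit.
#'
#' @param points data.frame with columns \code{concentration},
#'   \code{area} (one row per replicate measurement)
#' @param compound compound label
#' @param species ion species label
#' @param min_levels,min_replicates protocol minima
#' @return an \code{nts_calibration}: slope, intercept, r_squared,
#'   range, per-level summary
#' @export
fit_calibration <- function(points, compound = NA_character_,
                            species = NA_character_, min_levels = 5,
                            min_replicates = 3) {
  stopifnot(all(c("concentration", "area") %in% names(points)))
  lv <- sort(unique(points$concentration))
  if (length(lv) < min_levels) {
    stop("calibration needs at least ", min_levels,
         " distinct concentrations (got ", length(lv), ")")
  }
  reps <- table(points$concentration)
  if (any(reps < min_replicates)) {
    stop("calibration needs at least ", min_replicates,
         " replicates per concentration")
  }
  means <- tapply(points$area, points$concentration, mean)
  sds <- tapply(points$area, points$concentration, stats::sd)
  levels <- data.frame(concentration = as.numeric(names(means)),
                       mean_area = as.numeric(means),
                       rsd = as.numeric(sds / means))
  fit <- stats::lm(mean_area ~ concentration, data = levels)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((levels$mean_area - mean(levels$mean_area))^2)
  structure(list(compound = compound, species = species,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
                 range = range(levels$concentration),
                 levels = levels,
                 residuals = unname(stats::residuals(fit))),
            class = "nts_calibration")
}

#' @export
print.nts_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration> %s: area = %.4g * conc %+.4g, R2 = %.4f, range [%g, %g]\n",
    x$compound, x$slope, x$intercept, x$r_squared, x$range[1], x$range[2]))
  invisible(x)
}

#' Predicted area at a concentration
#' @param cal an \code{nts_calibration}
#' @param concentration concentration(s)
#' @return predicted area(s)
#' @export
predict_area <- function(cal, concentration) {
  cal$intercept + cal$slope * concentration
}

#' Quantify a peak area against a calibration
#'
#' Inverts the calibration line. Concentrations falling outside the
#' calibrated range are flagged (\code{below_range} / \code{above_range})
#' and not reported as numbers, mirroring how out-of-range peaks prevent
#' quantification.
#'
#' @param area measured peak area
#' @param cal an \code{nts_calibration}
#' @return list with \code{concentration} (NA when flagged) and
#'   \code{flag} (\code{"ok"}, \code{"below_range"}, \code{"above_range"})
#' @export
quantify <- function(area, cal) {
  if (cal$slope == 0) stop("zero calibration slope")
  conc <- (area - cal$intercept) / cal$slope
  flag <- if (conc < cal$range[1]) "below_range"
          else if (conc > cal$range[2]) "above_range"
          else "ok"
  list(concentration = if (flag == "ok") conc else NA_real_, flag = flag)
}

#' Normalized abundance of features within a sample
#'
#' Peak areas normalized to the total peak area of the sample, in
#' percent; sums to 100 and is invariant under uniform area scaling.
#'
#' @param areas numeric vector of peak areas (>= 0, not all zero)
#' @return percent abundances, same length
#' @export
normalized_abundance <- function(areas) {
  stopifnot(length(areas) >= 1, all(areas >= 0))
  total <- sum(areas)
  if (total == 0) stop("all areas are zero")
  areas / total * 100
}

.default_carbon_bins <- data.frame(
  label = c("C1-C5", "C6-C8", "C9-C12", "C13-C15", "C16-C20", "C21+"),
  lo = c(1, 6, 9, 13, 16, 21),
  hi = c(5, 8, 12, 15, 20, Inf),
  stringsAsFactors = FALSE
)

#' Group features by composition class and carbon number
#'
#' Aggregates assigned features of one sample into (composition class,
#' carbon-number bin) groups: summed area, percent of total sample area,
#' and the area-weighted mean O/C of each group and class. The literal
#' area share of each elemental grouping (group area / total sample
#' area) is the \code{pct} column. Unassigned features are excluded and
#' counted in the \code{n_unassigned} attribute. Empty groups are
#' absent, not zero rows.
#'
#' @param features data.frame with columns \code{formula} (NA when
#'   unassigned) and \code{area}
#' @param bins carbon-number bins (data.frame \code{label, lo, hi});
#'   defaults to C1-C5, C6-C8, C9-C12, C13-C15, C16-C20, C21+
#' @param sample sample label attached to the output
#' @return data.frame: \code{sample, comp_class, c_bin, n, area, pct,
#'   oc_w}, plus attributes \code{n_unassigned}, \code{total_area} and
#'   \code{class_oc_w} (per-class weighted O/C)
#' @export
group_composition <- function(features, bins = .default_carbon_bins,
                              sample = "sample") {
  ok <- !is.na(features$formula)
  n_unassigned <- sum(!ok)
  ft <- features[ok, , drop = FALSE]
  if (!nrow(ft)) stop("no assigned features to group")
  fl <- lapply(ft$formula, parse_formula)
  cc <- vapply(fl, comp_class, character(1))
  nC <- vapply(fl, function(f) f[["C"]], numeric(1))
  oc <- vapply(fl, function(f) f[["O"]] / f[["C"]], numeric(1))
  bin_idx <- vapply(nC, function(x) {
    which(x >= bins$lo & x <= bins$hi)[1]
  }, numeric(1))
  total <- sum(ft$area)
  key <- paste(cc, bins$label[bin_idx], sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sel <- key == k
    parts <- strsplit(k, "\r")[[1]]
    data.frame(sample = sample, comp_class = parts[1], c_bin = parts[2],
               n = sum(sel), area = sum(ft$area[sel]),
               pct = sum(ft$area[sel]) / total * 100,
               oc_w = sum(ft$area[sel] * oc[sel]) / sum(ft$area[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$comp_class, out$c_bin), , drop = FALSE]
  rownames(out) <- NULL
  cls_oc <- vapply(split(seq_len(nrow(ft)), cc), function(idx) {
    sum(ft$area[idx] * oc[idx]) / sum(ft$area[idx])
  }, numeric(1))
  attr(out, "n_unassigned") <- n_unassigned
  attr(out, "total_area") <- total
  attr(out, "class_oc_w") <- cls_oc
  out
}

#' Fraction of aromatic compounds in a group
#'
#' Count fraction (not area-weighted) of formulas with DBE/C strictly
#' greater than the threshold; DBE/C > 0.5 conventionally indicates
#' (poly)aromatic structures.
#'
#' @param formulas character vector of formula strings
#' @param threshold DBE/C threshold (strict inequality)
#' @return percent of formulas above the threshold
#' @export
aromatic_fraction <- function(formulas, threshold = 0.5) {
  stopifnot(length(formulas) >= 1)
  dbec <- vapply(formulas, function(s) {
    f <- parse_formula(s)
    dbe(f) / f[["C"]]
  }, numeric(1))
  mean(dbec > threshold) * 100
}

#' Source-category report for identified compounds
#'
#' Percent relative sample abundance per pollutant-source category:
#' each compound's peak area divided by the total sample peak area times
#' 100, summed by category. Compounds without a category map to
#' \code{"other"}. The total sample area should include all detected
#' features, so the per-category shares sum to at most 100 percent.
#'
#' @param identified data.frame with \code{compound} and \code{area}
#' @param categories named character vector mapping compound to source
#'   category
#' @param total_area total sample peak area (defaults to the identified
#'   area, in which case the categories partition 100 percent)
#' @return data.frame \code{category, area, pct} sorted by descending
#'   share
#' @export
source_report <- function(identified, categories,
                          total_area = sum(identified$area)) {
  stopifnot(all(c("compound", "area") %in% names(identified)),
            total_area > 0)
  cat_of <- categories[identified$compound]
  cat_of[is.na(cat_of)] <- "other"
  area <- tapply(identified$area, cat_of, sum)
  out <- data.frame(category = names(area), area = as.numeric(area),
                    pct = as.numeric(area) / total_area * 100,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct), , drop = FALSE]
  rownames(out) <- NULL
  out
}
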