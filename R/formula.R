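#' Molecular formulas
#'
#' A formula is a named integer vector of element counts over the supported
#' element set (C, H, N, O, S, Cl, Na, K, P), carrying class
#' \code{"nts_formula"}. All metric and mass arithmetic operates on this
#' representation. Phosphorus is accepted when parsing library compounds
#' (e.g. omethoate) but is never proposed by formula enumeration.
#'
#' @param ... element counts, e.g. \code{formula_of(C = 7, H = 8, O = 2)}
#' @return an \code{nts_formula} object
#' @examples
#' formula_of(C = 7, H = 8, O = 2)
#' @export
formula_of <- function(...) {
  counts <- c(...)
  if (length(counts) == 0) stop("formula needs at least one atom")
  bad <- setdiff(names(counts), .nts_elements)
  if (length(bad)) stop("unknown element symbol: ", paste(bad, collapse = ", "))
  full <- stats::setNames(integer(length(.nts_elements)), .nts_elements)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("element counts must be non-negative")
  if (sum(full) == 0) stop("formula needs at least one atom")
  structure(full, class = "nts_formula")
}

#' Parse a Hill-style formula string
#'
#' Accepts formulas written in Hill order (or any element order) with
#' optional count digits, e.g. \code{"C17H28O3S"} or \code{"CH4"}.
#'
#' @param text a single formula string
#' @return an \code{nts_formula}
#' @examples
#' parse_formula("C17H28O3S")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula string: ", text)
  }
  els <- sub("[0-9]*$", "", toks)
  ns <- sub("^[A-Z][a-z]?", "", toks)
  ns <- ifelse(ns == "", "1", ns)
  bad <- setdiff(els, .nts_elements)
  if (length(bad)) stop("unknown element symbol: ", paste(bad, collapse = ", "))
  counts <- tapply(as.integer(ns), els, sum)
  do.call(formula_of, as.list(counts))
}

#' Format a formula in Hill order
#'
#' C first, H second, remaining elements alphabetically; unit counts omit
#' the digit. \code{parse_formula(format_formula(f))} round-trips.
#'
#' @param f an \code{nts_formula}
#' @return a character scalar
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "nts_formula"))
  rest <- sort(setdiff(.nts_elements[f[.nts_elements] > 0], c("C", "H")))
  ord <- c(intersect(c("C", "H"), .nts_elements[f > 0]), rest)
  paste0(vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.nts_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

#' @export
format.nts_formula <- function(x, ...) format_formula(x)

#' Add two formulas element-wise
#' @param f1,f2 \code{nts_formula} objects
#' @return their union as an \code{nts_formula}
#' @export
formula_add <- function(f1, f2) {
  structure(stats::setNames(as.integer(unclass(f1) + unclass(f2)),
                            .nts_elements),
            class = "nts_formula")
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of most-abundant-isotope atomic masses; additive under
#' \code{formula_add}.
#'
#' @param f an \code{nts_formula}
#' @return mass in Da
#' @examples
#' monoisotopic_mass(parse_formula("C7H8O2")) # 124.0524
#' @export
monoisotopic_mass <- function(f) {
  stopifnot(inherits(f, "nts_formula"))
  sum(unclass(f) * .nts_monoiso[.nts_elements])
}

#' Nominal (integer) mass of a neutral formula
#' @param f an \code{nts_formula}
#' @return integer Da
#' @examples
#' nominal_mass(parse_formula("C17H28O3S")) # 312
#' @export
nominal_mass <- function(f) {
  stopifnot(inherits(f, "nts_formula"))
  as.integer(sum(unclass(f) * .nts_nominal[.nts_elements]))
}

#' Double-bond equivalents
#'
#' DBE = C - (H + Cl + Na + K)/2 + (N + P)/2 + 1. Halogens and the
#' monovalent metals count as hydrogen; N and P are treated as trivalent.
#' Even-electron neutrals have integer DBE, which the erroneous-formula
#' filter exploits.
#'
#' @param f an \code{nts_formula}
#' @return DBE (a multiple of 0.5)
#' @examples
#' dbe(parse_formula("C17H28O3S")) # 4
#' @export
dbe <- function(f) {
  stopifnot(inherits(f, "nts_formula"))
  f[["C"]] - (f[["H"]] + f[["Cl"]] + f[["Na"]] + f[["K"]]) / 2 +
    (f[["N"]] + f[["P"]]) / 2 + 1
}

#' Composition class of a formula
#'
#' Class label determined solely by which heteroatoms are present:
#' CH, CHO, CHON, CHOS, CHONS, CHN, CHS, CHNS, with a "Cl" suffix when
#' chlorine is present (surface-water mode allows Cl), and "other" for
#' formulas outside the lattice (e.g. no carbon or no hydrogen).
#'
#' @param f an \code{nts_formula}
#' @return a character scalar
#' @export
comp_class <- function(f) {
  stopifnot(inherits(f, "nts_formula"))
  if (f[["C"]] == 0 || f[["H"]] == 0) return("other")
  cls <- paste0("CH",
                if (f[["O"]] > 0) "O" else "",
                if (f[["N"]] > 0) "N" else "",
                if (f[["S"]] > 0) "S" else "")
  if (f[["Cl"]] > 0) cls <- paste0(cls, "Cl")
  cls
}

#' Chemical metrics of a formula
#'
#' Computes the compositional metrics used throughout environmental
#' high-resolution MS: monoisotopic and nominal MW, DBE and DBE/C,
#' elemental ratios (O/C, H/C, N/C, S/C), the average carbon oxidation
#' state OSc = 2 O/C - H/C, and the aromaticity index
#' AI = (1 + C - O - S - 0.5 H) / (C - O - S - N - P), clamped to 0 when
#' its numerator or denominator is <= 0. With \code{modified = TRUE} the
#' modified aromaticity index is returned instead (half the oxygen counted
#' in both numerator and denominator).
#'
#' @param f an \code{nts_formula} with at least one carbon
#' @param modified use the modified aromaticity index (0.5 O)
#' @return a one-row data.frame with columns \code{formula, mw_mono,
#'   mw_nominal, dbe, dbe_c, oc, hc, nc, sc, osc, ai, comp_class}
#' @examples
#' metrics(parse_formula("C16H26O3S"))$oc # 0.1875
#' @export
metrics <- function(f, modified = FALSE) {
  stopifnot(inherits(f, "nts_formula"))
  C <- f[["C"]]
  if (C < 1) stop("metrics require at least one carbon")
  H <- f[["H"]]; N <- f[["N"]]; O <- f[["O"]]; S <- f[["S"]]; P <- f[["P"]]
  ofac <- if (modified) 0.5 * O else O
  ai_num <- 1 + C - ofac - S - 0.5 * H
  ai_den <- C - ofac - S - N - P
  ai <- if (ai_num <= 0 || ai_den <= 0) 0 else ai_num / ai_den
  d <- dbe(f)
  data.frame(
    formula = format_formula(f),
    mw_mono = monoisotopic_mass(f),
    mw_nominal = nominal_mass(f),
    dbe = d,
    dbe_c = d / C,
    oc = O / C,
    hc = H / C,
    nc = N / C,
    sc = S / C,
    osc = 2 * O / C - H / C,
    ai = ai,
    comp_class = comp_class(f),
    stringsAsFactors = FALSE
  )
}

#' Metric table for a set of formulas
#'
#' @param formulas a character vector of formula strings or a list of
#'   \code{nts_formula} objects
#' @param modified use the modified aromaticity index
#' @return a data.frame, one row per formula, in \code{\link{metrics}}
#'   column order
#' @export
metric_table <- function(formulas, modified = FALSE) {
  fl <- lapply(formulas, function(f) {
    if (inherits(f, "nts_formula")) f else parse_formula(f)
  })
  do.call(rbind, lapply(fl, metrics, modified = modified))
}
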