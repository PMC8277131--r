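#' Ion species (adducts, dimers, neutral losses)
#'
#' An ion species describes how a neutral molecule M appears as a singly
#' charged ion: a label, the mass delta added to the neutral monoisotopic
#' mass (electron mass included, so \code{[M+H]+} adds one proton mass),
#' a charge sign and the multiplicity of M in the ion (2 for dimers).
#'
#' @param label species label, e.g. \code{"[M+H]+"}
#' @param delta mass delta in Da applied to n_m * neutral mass
#' @param polarity \code{"positive"} or \code{"negative"}
#' @param n_m number of M units in the ion (2 for \code{[2M+H]+})
#' @return an \code{nts_ion} object
#' @export
ion_species <- function(label, delta, polarity, n_m = 1L) {
  stopifnot(polarity %in% c("positive", "negative"))
  ends_plus <- grepl("\\+$", label)
  ends_minus <- grepl("(-|−)$", label)
  sign_ok <- (polarity == "positive" && ends_plus) ||
    (polarity == "negative" && ends_minus)
  if (!sign_ok) stop("polarity of label does not match charge sign: ", label)
  structure(list(label = label, delta = delta, polarity = polarity,
                 n_m = as.integer(n_m)),
            class = "nts_ion")
}

#' @export
print.nts_ion <- function(x, ...) {
  cat(sprintf("<ion> %s  delta %+0.6f Da  (%s)\n", x$label, x$delta,
              x$polarity))
  invisible(x)
}

# deltas built from atomic masses so the electron correction is exact
.nts_ion_deltas <- function() {
  H <- .nts_monoiso[["H"]]; Na <- .nts_monoiso[["Na"]]
  K <- .nts_monoiso[["K"]]; N <- .nts_monoiso[["N"]]
  O <- .nts_monoiso[["O"]]; C <- .nts_monoiso[["C"]]
  Cl <- .nts_monoiso[["Cl"]]; e <- .nts_electron_mass
  list(
    "[M+H]+"      = ion_species("[M+H]+",       H - e,                "positive"),
    "[M+Na]+"     = ion_species("[M+Na]+",      Na - e,               "positive"),
    "[M+K]+"      = ion_species("[M+K]+",       K - e,                "positive"),
    "[M+NH4]+"    = ion_species("[M+NH4]+",     N + 4 * H - e,        "positive"),
    "[M+H-H2O]+"  = ion_species("[M+H-H2O]+",   H - e - (2 * H + O),  "positive"),
    "[2M+H]+"     = ion_species("[2M+H]+",      H - e,                "positive", n_m = 2L),
    "[M-H]-"      = ion_species("[M-H]-",       -H + e,               "negative"),
    "[M+Cl]-"     = ion_species("[M+Cl]-",      Cl + e,               "negative"),
    "[M+HCOO]-"   = ion_species("[M+HCOO]-",    C + 2 * O + H + e,    "negative"),
    "[M-H-H2O]-"  = ion_species("[M-H-H2O]-",   -H + e - (2 * H + O), "negative"),
    "[2M-H]-"     = ion_species("[2M-H]-",      -H + e,               "negative", n_m = 2L)
  )
}

#' Look up a built-in ion species by label
#' @param label e.g. \code{"[M-H]-"}
#' @return an \code{nts_ion}
#' @export
get_ion <- function(label) {
  if (inherits(label, "nts_ion")) return(label)
  tab <- .nts_ion_deltas()
  if (!label %in% names(tab)) {
    stop("unknown ion species: ", label,
         " (known: ", paste(names(tab), collapse = ", "), ")")
  }
  tab[[label]]
}

#' m/z of a singly charged ion of a neutral formula
#'
#' @param f neutral \code{nts_formula}
#' @param sp an \code{nts_ion} or its label
#' @return m/z in Th
#' @examples
#' ion_mz(parse_formula("C7H8O2"), "[M-H]-") # 123.0452
#' @export
ion_mz <- function(f, sp) {
  sp <- get_ion(sp)
  sp$n_m * monoisotopic_mass(f) + sp$delta
}

#' Default ESI artifact table
#'
#' The adduct/dimer/neutral-loss species screened for when grouping
#' co-eluting features of the same neutral molecule, per polarity, with
#' the co-elution and m/z matching tolerances. Fully user-overridable.
#'
#' @param polarity \code{"positive"} or \code{"negative"}
#' @param rt_tol co-elution tolerance in minutes
#' @param mz_tol_ppm m/z matching tolerance in ppm
#' @param preferred preferred (reported) adduct label; defaults to
#'   \code{[M+H]+} / \code{[M-H]-}
#' @return an \code{nts_artifact_table}: list of species plus tolerances
#' @export
artifact_table <- function(polarity,
                           rt_tol = 0.1,
                           mz_tol_ppm = 5,
                           preferred = NULL) {
  stopifnot(polarity %in% c("positive", "negative"), rt_tol > 0,
            mz_tol_ppm > 0)
  all_sp <- .nts_ion_deltas()
  sp <- Filter(function(s) s$polarity == polarity, all_sp)
  if (is.null(preferred)) {
    preferred <- if (polarity == "positive") "[M+H]+" else "[M-H]-"
  }
  stopifnot(preferred %in% names(sp))
  structure(list(species = sp, polarity = polarity, rt_tol = rt_tol,
                 mz_tol_ppm = mz_tol_ppm, preferred = preferred),
            class = "nts_artifact_table")
}
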