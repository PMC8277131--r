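#' Theoretical isotope pattern (A, A+1, A+2)
#'
#' Relative intensities of the first three isotopologue clusters of a
#' singly charged ion, from natural isotope abundances. The distribution
#' is built by atom-wise convolution of each element's single-atom
#' isotope distribution, truncated beyond A+2; the principal (A) peak is
#' normalized to 1. Each cluster's m/z is the abundance-weighted mean of
#' its contributing exact mass shifts added to the ion m/z (the A+2
#' cluster of a sulfur compound sits near +1.996, not +2.007).
#'
#' @param f neutral \code{nts_formula}
#' @param sp ion species (label or \code{nts_ion}); \code{NULL} for the
#'   neutral pattern (m/z column then holds neutral mass)
#' @return data.frame with columns \code{shift} (0,1,2), \code{mz},
#'   \code{rel} (A = 1)
#' @examples
#' isotope_pattern(parse_formula("C1"))$rel[2] # ~0.0108
#' @export
isotope_pattern <- function(f, sp = NULL) {
  stopifnot(inherits(f, "nts_formula"))
  # per-shift probability p and probability-weighted mass shift m
  p <- c(1, 0, 0)
  m <- c(0, 0, 0)
  counts <- unclass(f)
  if (!is.null(sp)) counts <- counts * get_ion(sp)$n_m
  for (el in .nts_elements) {
    n <- counts[[el]]
    if (n == 0) next
    iso <- .nts_isotopes[[el]]
    if (nrow(iso) == 1) next
    for (i in seq_len(n)) {
      np <- numeric(3); nm <- numeric(3)
      for (k in 0:2) {
        if (p[k + 1] == 0 && m[k + 1] == 0) next
        for (j in seq_len(nrow(iso))) {
          s <- k + iso[j, "shift"]
          if (s > 2) next
          ab <- iso[j, "ab"]
          np[s + 1] <- np[s + 1] + p[k + 1] * ab
          nm[s + 1] <- nm[s + 1] + m[k + 1] * ab + p[k + 1] * ab * iso[j, "dm"]
        }
      }
      p <- np; m <- nm
    }
  }
  mean_dm <- ifelse(p > 0, m / p, 0:2)
  base_mz <- if (is.null(sp)) monoisotopic_mass(f) else ion_mz(f, sp)
  data.frame(shift = 0:2, mz = base_mz + mean_dm, rel = p / p[1])
}
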