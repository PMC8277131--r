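# Atomic constants for the supported element set.
#
# Monoisotopic masses are the most-abundant-isotope masses (CODATA/AME),
# kept to >= 6 dp because a 3 ppm gate at m/z 123 is +/- 0.0004 Da.
# P is supported for parsing library compounds (e.g. organophosphate
# pesticides) but excluded from formula enumeration.

.nts_elements <- c("C", "H", "N", "O", "S", "Cl", "Na", "K", "P")

.nts_monoiso <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.00307400480,
  O  = 15.99491461960,
  S  = 31.97207100,
  Cl = 34.96885268,
  Na = 22.98976928090,
  K  = 38.96370668,
  P  = 30.97376163
)

# integer mass numbers of the most abundant isotopes
.nts_nominal <- c(
  C = 12L, H = 1L, N = 14L, O = 16L, S = 32L,
  Cl = 35L, Na = 23L, K = 39L, P = 31L
)

.nts_electron_mass <- 0.00054857990946
.nts_proton_mass <- .nts_monoiso[["H"]] - .nts_electron_mass

# Natural isotope abundances and exact mass shifts relative to the
# principal isotope, truncated at +2 mass units (A, A+1, A+2 window).
# Each element maps to a matrix with columns: integer shift, exact mass
# shift (Da), abundance. Abundances from the IUPAC representative values.
.nts_isotopes <- list(
  C = cbind(shift = c(0, 1),
            dm = c(0, 1.0033548378),
            ab = c(0.9893, 0.0107)),
  H = cbind(shift = c(0, 1),
            dm = c(0, 1.0062767458),
            ab = c(0.999885, 0.000115)),
  N = cbind(shift = c(0, 1),
            dm = c(0, 0.9970348934),
            ab = c(0.99636, 0.00364)),
  O = cbind(shift = c(0, 1, 2),
            dm = c(0, 1.0042169447, 2.0042449972),
            ab = c(0.99757, 0.00038, 0.00205)),
  S = cbind(shift = c(0, 1, 2),
            dm = c(0, 0.9993877354, 1.9957958900),
            ab = c(0.9499, 0.0075, 0.0425)),
  Cl = cbind(shift = c(0, 2),
             dm = c(0, 1.9970499000),
             ab = c(0.7576, 0.2424)),
  K = cbind(shift = c(0, 2),
            dm = c(0, 1.9981199000),
            ab = c(0.932581, 0.067302)),
  Na = cbind(shift = 0, dm = 0, ab = 1),
  P  = cbind(shift = 0, dm = 0, ab = 1)
)
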