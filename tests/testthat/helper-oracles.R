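# Independent brute-force oracles used to validate the fast
# implementations. Kept deliberately naive: they enumerate everything.

# monoisotopic masses, restated locally so the oracle does not depend on
# the package internals
.oracle_masses <- c(C = 12.0, H = 1.00782503207, N = 14.00307400480,
                    O = 15.99491461960, S = 31.97207100, Cl = 34.96885268)
.oracle_electron <- 0.00054857990946

# full formula grid up to m/z ~520 under a mode's element limits;
# built once per session and cached
.oracle_grid_cache <- new.env(parent = emptyenv())

oracle_formula_grid <- function(cl_max = 0) {
  key <- paste0("cl", cl_max)
  if (!is.null(.oracle_grid_cache[[key]])) {
    return(.oracle_grid_cache[[key]])
  }
  g <- expand.grid(C = 1:41, H = 0:89, N = 0:5, O = 0:31, S = 0:2,
                   Cl = 0:cl_max)
  g <- g[g$H <= 2 * g$C + g$N + 2, , drop = FALSE]
  g$mass <- g$C * .oracle_masses[["C"]] + g$H * .oracle_masses[["H"]] +
    g$N * .oracle_masses[["N"]] + g$O * .oracle_masses[["O"]] +
    g$S * .oracle_masses[["S"]] + g$Cl * .oracle_masses[["Cl"]]
  g <- g[g$mass <= 520, , drop = FALSE]
  .oracle_grid_cache[[key]] <- g
  g
}

# every neutral formula whose ion lies strictly within tol_ppm of mz;
# species is "[M-H]-" or "[M+H]+"
oracle_enumerate <- function(mz, species, tol_ppm = 3, cl_max = 0) {
  delta <- switch(species,
                  "[M-H]-" = -.oracle_masses[["H"]] + .oracle_electron,
                  "[M+H]+" = .oracle_masses[["H"]] - .oracle_electron,
                  stop("oracle only knows [M-H]- and [M+H]+"))
  g <- oracle_formula_grid(cl_max)
  target <- mz - delta
  hit <- g[abs(g$mass - target) < mz * tol_ppm * 1e-6, , drop = FALSE]
  if (!nrow(hit)) return(character(0))
  sort(apply(hit, 1, function(r) {
    paste0(
      "C", r[["C"]], "H", r[["H"]],
      if (r[["N"]] > 0) paste0("N", r[["N"]]) else "",
      if (r[["O"]] > 0) paste0("O", r[["O"]]) else "",
      if (r[["S"]] > 0) paste0("S", r[["S"]]) else "",
      if (r[["Cl"]] > 0) paste0("Cl", r[["Cl"]]) else "")
  }))
}

# canonical "CnHn..." key for comparing formula sets with the oracle
canonical_counts <- function(formula_string) {
  f <- ntscreen::parse_formula(formula_string)
  paste0("C", f[["C"]], "H", f[["H"]],
         if (f[["N"]] > 0) paste0("N", f[["N"]]) else "",
         if (f[["O"]] > 0) paste0("O", f[["O"]]) else "",
         if (f[["S"]] > 0) paste0("S", f[["S"]]) else "",
         if (f[["Cl"]] > 0) paste0("Cl", f[["Cl"]]) else "")
}

# isotope-pattern oracle: explicit multinomial enumeration of all
# isotopologues with total nominal shift <= 2 (an independent route from
# the sequential convolution in the implementation)
.oracle_isotopes <- list(
  C = list(p = c(0.9893, 0.0107), shift = c(0, 1)),
  H = list(p = c(0.999885, 0.000115), shift = c(0, 1)),
  N = list(p = c(0.99636, 0.00364), shift = c(0, 1)),
  O = list(p = c(0.99757, 0.00038, 0.00205), shift = c(0, 1, 2)),
  S = list(p = c(0.9499, 0.0075, 0.0425), shift = c(0, 1, 2)),
  Cl = list(p = c(0.7576, 0.2424), shift = c(0, 2)),
  K = list(p = c(0.932581, 0.067302), shift = c(0, 2))
)

oracle_isotope_pattern <- function(counts) {
  # counts: named vector of element counts
  # per element, enumerate heavy-isotope pick combinations (k per heavy
  # isotope), keep total shift <= 2, with exact multinomial probability
  per_el <- lapply(names(counts), function(el) {
    n <- counts[[el]]
    iso <- .oracle_isotopes[[el]]
    if (is.null(iso) || n == 0) {
      return(data.frame(shift = 0, prob = 1))
    }
    heavy <- seq_along(iso$p)[-1]
    combos <- expand.grid(lapply(heavy, function(j) 0:2))
    rows <- list()
    for (i in seq_len(nrow(combos))) {
      ks <- as.numeric(combos[i, ])
      if (sum(ks) > n) next
      tot_shift <- sum(ks * iso$shift[heavy])
      if (tot_shift > 2) next
      k0 <- n - sum(ks)
      prob <- factorial(n) / prod(factorial(c(k0, ks))) *
        prod(c(iso$p[1]^k0, iso$p[heavy]^ks))
      rows[[length(rows) + 1]] <- data.frame(shift = tot_shift,
                                             prob = prob)
    }
    agg <- do.call(rbind, rows)
    stats::aggregate(prob ~ shift, agg, sum)
  })
  # convolve the per-element shift distributions (over shift 0..2)
  dist <- c(1, 0, 0)
  for (d in per_el) {
    nd <- numeric(3)
    for (i in seq_len(nrow(d))) {
      s <- d$shift[i]
      for (k in 0:(2 - s)) nd[k + s + 1] <- nd[k + s + 1] +
          dist[k + 1] * d$prob[i]
    }
    dist <- nd
  }
  dist / dist[1]
}

# random chemically plausible formula within the screening limits
random_legal_formula <- function() {
  repeat {
    C <- sample(5:20, 1)
    O <- sample(0:min(8, 3 * C), 1)
    N <- sample(0:3, 1)
    S <- sample(0:1, 1)
    # integer DBE needs H = N (mod 2); DBE in [0, C] keeps H/C plausible
    d <- sample(0:min(8, C), 1)
    H <- 2 * C + 2 + N - 2 * d
    if (H < 1) next
    hc <- H / C
    if (hc < 0.3 || hc > 2.5) next
    f <- ntscreen::formula_of(C = C, H = H, N = N, O = O, S = S)
    m <- ntscreen::monoisotopic_mass(f)
    if (m >= 100 && m <= 420) return(f)
  }
}
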