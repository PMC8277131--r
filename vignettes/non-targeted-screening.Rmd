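---
title: "Methods: non-targeted LC-HRMS screening with ntscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-targeted LC-HRMS screening with ntscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntscreen)
```

# The problem and the model

Non-targeted screening asks: given centroided LC-MS runs of a complex
environmental mixture, which chromatographic features are real
compounds, what are their molecular formulas, which can be identified
against MS² libraries, and how does the composition of samples
compare? `ntscreen` implements that workflow as a chain of small,
individually testable operations. This vignette records the model
behind each stage, the tunable parameters with their defaults and
units, the numerical choices made where the design was genuinely
open, and what the synthetic-data generator does and does not
emulate.

## Formula arithmetic

A formula is a count vector over C, H, N, O, S, Cl, Na, K, P.
Monoisotopic masses use most-abundant-isotope atomic masses to ≥ 6
decimal places, and all ion m/z values are electron-corrected: at a
3 ppm gate near m/z 123 the window is ± 0.0004 Da while the electron
mass is 0.00055 Da, so ignoring it would systematically bias
assignment. Supported ion species are singly charged adducts, dimers
and water-loss species; multiply charged and radical ions are out of
scope.

Double-bond equivalents are computed as
DBE = C − (H + Cl + Na + K)/2 + (N + P)/2 + 1, counting halogens and
the monovalent metals as hydrogen. This keeps sodiated neutrals at
integer DBE, which matters because the erroneous-formula filter uses
integer DBE as an even-electron plausibility rule.

Two aromaticity-index conventions circulate in the environmental
FTMS literature; we implement the classical form
AI = (1 + C − O − S − 0.5 H)/(C − O − S − N − P), clamped to 0 when
numerator or denominator is non-positive, and expose the modified
form (half the oxygen) as an option, since both are standard and the
choice materially shifts the aromatic fraction of oxidized mixtures.
The average carbon oxidation state is OSc = 2·O/C − H/C with
heteroatoms ignored, following the cited convention.

Composition classes (CH, CHO, CHON, CHOS, CHONS, with a `Cl` suffix
when chlorine is present) are determined solely by which heteroatoms
are nonzero. Keeping Cl-containing classes distinct rather than
folding them into "other" preserves information in surface-water
mode, where Cl is a legal formula element.

Printed molecular weights in compositional tables are nominal
(integer) masses. For the compound classes involved the rounded
monoisotopic mass agrees with the nominal mass, so nothing is lost,
and nominal masses are the convention in carbon-number groupings.

## Isotope patterns

Theoretical A/A+1/A+2 intensities come from atom-wise convolution of
single-atom isotope distributions, truncated beyond +2 and normalized
to the principal peak; the test suite checks this against an
independent multinomial-enumeration oracle to within 1 %. Each
cluster's m/z is the abundance-weighted mean of its contributing
exact mass shifts — for sulfur compounds A+2 sits near +1.996, not
+2.007, which is why observed isotopologues are measured in ± 0.015 Da
windows around mz + k·1.00336: wide enough to cover the ¹³C₂/³⁴S/¹⁸O
spread at the resolutions emulated here. Patterns for adduct ions
scale the M backbone (dimers count it twice); isotopes of the adduct
atom itself are neglected, which is exact for Na and negligible for
H/K preferred adducts — chloride-adduct patterns are *not* modelled,
and [M+Cl]⁻ species are only ever grouped away as artifacts, never
assigned.

## Peak detection

EICs sum centroid intensities in half-open windows
[low, high). Unit-mass windows are `[floor(mz), floor(mz)+1)`;
accurate-mass windows default to ± 5 ppm, consistent with the
≈ ± 4 ppm extraction windows used in practice. Baseline noise is
1.4826 × MAD of the EIC outside the peak's own region — the vendor
S/N definition is undisclosed, and a robust scale estimator is
reproducible and insensitive to sparse peaks. S/N is apex divided by
that noise; a noise-free window reports `Inf` as a sentinel.

A peak requires (defaults): S/N > 3, apex ≥ 3·10⁴ counts, and ≥ 3
consecutive scans above the counting level. The counting level is
max(baseline + noise, 0.5 % of apex) — the published rule names the
scan count but not its reference level, so the level is documented
here as a package choice; the 0.5 %-of-apex floor keeps the rule
meaningful for intense peaks over near-zero baselines. Peak bounds
are the nearest flanking local minimum or baseline crossing. Areas
are trapezoidal integrals over retention time (intensity · min).

This design reproduces the unit- vs accurate-mass mechanism: an
interference elsewhere in the same unit window inflates the
unit-window noise and depresses unit-mode S/N while the accurate
window is untouched. The acceptance suite asserts the inequality
(accurate ≥ unit) rather than any particular improvement factor,
because the factor depends on the interference intensity, which is
free in the simulation.

Retention-time alignment is an anchor-based monotone piecewise-linear
warp (isotonic regression of reference RT on run RT over matched
intense features), falling back to identity with a warning when no
anchors match. It is off by default for single-run analyses.

## Formula assignment

Candidates for an ion m/z are all neutral formulas whose theoretical
ion m/z lies strictly within ± 3 ppm, under per-mode element limits:
N ≤ 5 and S ≤ 2 everywhere, Cl ≤ 3 only in surface-water mode, and
(opt-in) Na ≤ 2 / K ≤ 1 in positive mode. "Unlimited" C, H, O are
capped operationally at C ≤ mass/12, O ≤ mass/15.99, H ≤ 2C + N + 2 —
needed for termination and provably unable to exclude anything inside
the tolerance. In-formula metals default to off because they cause
pathological candidate growth; sodium is normally evidence of an
[M+Na]⁺ adduct, not of a sodiated neutral. The enumerator runs
lexicographically over heteroatoms with a closed-form C/H inner
solve; the test suite proves set-equality against a naive
enumerate-everything oracle for random m/z ≤ 500.

Isotope verification passes a candidate when every *observed*
isotopologue is within ± 30 % (relative) of theory. Whether that
tolerance is relative or absolute-percentage is not documented for
the reference implementation; relative was adopted as the chemically
meaningful reading. A *missing* A+1/A+2 fails the check only when the
theoretical intensity, scaled by the observed A intensity, exceeds
the detection floor (default: the minimum peak intensity) — absence
of an unobservable isotopologue is not evidence against a formula.

Erroneous-formula rules (integer DBE, DBE ≥ 0, 0.2 ≤ H/C ≤ 3.1,
O/C ≤ 3) each record exactly one rule name per rejection. Assignment
picks the lowest-|ppm| survivor; when a second survivor lies within
1 ppm the feature is reported `ambiguous` with both formulas rather
than silently picking one, since no tie-break rule is documented for
the reference workflow.

## Adduct grouping and blanks

Co-eluting features (default RT tolerance 0.1 min, m/z tolerance
5 ppm) whose m/z differences match the artifact table are merged into
components; each component reports one preferred adduct ([M−H]⁻ /
[M+H]⁺ unless overridden). The default artifact table is standard ESI
chemistry — negative: [M−H]⁻, [M+Cl]⁻, [M+HCOO]⁻, [2M−H]⁻,
[M−H−H₂O]⁻; positive: [M+H]⁺, [M+Na]⁺, [M+K]⁺, [M+NH₄]⁺, [2M+H]⁺,
[M+H−H₂O]⁺ — and fully user-overridable, since the reference table is
supplementary-only and could not be carried over verbatim.

Two grouping modes exist because commercial software is documented to
find [M+Na]⁺ only after [M+H]⁺: `vendor_compat` seeds components only
from the primary-adduct hypothesis (reproducing the limitation — a
compound seen exclusively as [M+Na]⁺ is never recognized), while
`independent` seeds from every species and, for positive-mode
singletons, hands the Na/K hypotheses to formula assignment to
adjudicate. The fixture of four sodium-only analytes is recovered
fully in independent mode and not at all in vendor-compat mode.

Blank subtraction removes a sample feature matching a blank feature
(m/z ± 5 ppm, RT ± 0.1 min) unless its area is ≥ 3 × the blank area;
both blanks are applied sequentially and matched-but-retained
features carry their ratio. The exact reference criterion lives in
unavailable supplementary material; the ratio rule is therefore a
documented package decision, chosen because it is monotone,
idempotent and conservative for genuine sample compounds.

## MS² matching and confidence

Similarity is 100 × the cosine of square-root-intensity vectors after
greedy fragment pairing (tolerance 0.01 Da, highest-intensity first,
ties to smallest Δm/z). Proprietary library scores cannot be
replicated, so published percent thresholds (82/85/91) are treated as
configuration values on *this* score, not as comparable quantities.
Identification confidence follows the conventional 5-level scale;
level 1 additionally requires RT agreement with the authentic
standard within ± 0.3 min (configurable).

## Quantification and groupings

Calibrations are unweighted ordinary least squares of mean area on
concentration over ≥ 5 levels × 3 replicates (the fit is on replicate
means; per-level RSDs are stored). Weighting is left out because the
reference protocol does not state any. Quantification inverts the
line and flags concentrations outside the calibrated range instead of
reporting numbers.

Compositional groupings aggregate by composition class × carbon bins
(defaults C1–C5, C6–C8, C9–C12, C13–C15, C16–C20, C21+ — chosen to
contain the conventional C6–C8 and C16–C20 reporting groups).
"Weighted O/C" is implemented as the area-weighted mean O/C of a
group; the literal area share of the group (group area / total sample
area) is emitted alongside as `pct`, because the figure-caption
wording describing the weighted ratio is ambiguous between the two
readings. The aromatic fraction is the count (not area) fraction of
formulas with DBE/C strictly > 0.5.

# The synthetic-data generator

The generator emulates centroided Orbitrap-style runs: one centroid
per isotopologue per scan (Gaussian in RT), isotopologue intensities
from the theoretical pattern, per-centroid Gaussian mass jitter
(default σ = 1 ppm), multiplicative intensity noise (default CV 2 %),
and a chemical background of uniform-m/z, exponential-intensity
centroids (default 0.2 per scan per Th with mean 2·10³ counts) — the
simplest background that exercises S/N estimation and blank logic.
Runs default to 1 scan/s over a 10-min gradient. Everything is
bit-exactly reproducible from the noise seed.

It does **not** emulate profile peak shapes, resolution-dependent
centroid merging, space-charge effects, retention-time drift physics,
ionization suppression, or realistic background correlation
structure. Passing tests therefore demonstrate the correctness of the
*algorithms* under the stated noise model, not instrument-level
performance on real matrices; dataset-level figures from real
campaigns (detection percentages, compound counts per sample) are not
reproducible at desk scale and are deliberately not asserted.

Problem sizes used in the test and acceptance suites — 50-analyte
runs at 601 scans for end-to-end recovery, 200 random m/z per mode
for oracle equivalence, 5-level triplicate calibration series — were
chosen as the smallest sizes at which the statistical assertions
(≥ 95 % recovery, ≤ 10 % quantification error, R² > 0.99) are
meaningful.

# Degenerate inputs and numerical details

* Empty candidate lists, empty peak tables and empty feature tables
  flow through every stage as valid empty results; only operations
  whose contract requires data (noise estimation with < 10 baseline
  scans, metrics without carbon, calibration below protocol minima)
  raise errors.
* Noise-free S/N is reported as `Inf`, never NaN.
* Trapezoidal integration bounds tolerate 1e-9 relative grid
  round-off so closed-form fixtures integrate exactly.
* Warp functions are forced monotone (isotonic fit plus a `cummax`
  guard) and extended beyond the anchor range by the boundary offset.
* Mass-spectral base64 payloads in written mzML are single-line;
  scan tables carry per-scan RTs in a header comment so empty scans
  round-trip.

# Known limitations

* Charge states |z| > 1, radical ions and isotope-weighted (average)
  molecular weights are out of scope.
* Chloride-adduct isotope patterns are not modelled (see above).
* Only a single S/N gate is applied; reference software applies two
  (spectrum selection and compound detection), whose interaction is
  documented to cause false < LOD calls — that dual-gate behaviour is
  intentionally not replicated.
* MSP/MGF are the only library formats; vendor-format libraries must
  be converted externally.
* Normalized abundance does not correct for ESI ionization
  efficiency; compositional shares are operational, not molar.
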