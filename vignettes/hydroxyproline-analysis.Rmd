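---
title: "Quantifying peptidyl-proline 4-hydroxylation by LC-ESI-MS: methods and models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peptidyl-proline 4-hydroxylation by LC-ESI-MS: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyproquant)
```

## The problem

Plant cells convert peptidyl-proline to 4-hydroxyproline (Hyp) through
prolyl 4-hydroxylases (P4Hs), Fe(II)/2-oxoglutarate-dependent dioxygenases
resident in the secretory pathway. On recombinant human glycoproteins
produced in *Nicotiana benthamiana* — IgA1 and erythropoietin being the
prominent biotechnological cases — Hyp is an unwanted, potentially
immunogenic modification and the anchor for plant-specific arabinose
O-glycans. Characterizing which prolines a P4H touches, how strongly, and
with what sequence preference is therefore a quantification problem with
three measurable layers:

1. **Stoichiometry** — what fraction of a peptide population carries
   0, 1, ..., k hydroxyprolines;
2. **Site** — which proline in the sequence carries each oxidation;
3. **Kinetics** — the Michaelis constant and maximal velocity of the enzyme
   on a peptide substrate.

`hyproquant` implements all three layers on LC-ESI-MS data, together with a
synthetic-data generator that emulates the relevant features of Q-TOF
measurements so every stage can be validated end to end against known
ground truth.

## Mass and envelope arithmetic

Each +16 Da mass increment on a peptide marks one additional hydroxyproline
(oxidation, +15.994915 Da, +O, restricted to Pro). Cysteines are treated as
carbamidomethylated (+57.021464 Da, +C2H3NO), reflecting iodoacetamide
alkylation during sample preparation. Monoisotopic masses are summed from a
single embedded atomic-constants table (`isotope_table()`), documented to
six decimals, so mass and envelope computations share one authority. In an
ion of charge z, one oxidation shifts m/z by 15.994915/z — the familiar
16 / 8 / 5.3 Da spacings at charges 1-3.

Isotope envelopes use the aggregated (unit-spaced) model: per-element
isotope patterns are convolved into a nominal-offset abundance vector, with
the monoisotopic peak at offset 0 and peaks spaced by the ¹³C-¹²C mass
difference (1.0033548 Da). Fine isotope structure is deliberately out of
scope: the quantification below only ever sums the first few nominal peaks,
for which the aggregated model is exact to well below the tolerances used.
The convolution is verified in the test suite against an independent
multinomial-expansion oracle to 1e-9.

## Stoichiometry from extracted ion chromatograms

For a peptide with up to `max_ox` hydroxyprolines, the abundance of the
n-oxidized species is taken as the sum, over all observed charge states and
over the first four isotopic peaks, of the integrated extracted-ion-
chromatogram (EIC) areas at the species' theoretical m/z values
(`quantify_stoichiometry()`). Fractions are the abundances normalized to
100%. Positional isomers share a composition and therefore pool into one
species per oxidation count; isomer resolution is the localization module's
job.

Two derived statistics mirror the standard reporting layout:

- `average_hyp()` — the expected Hyp count, `sum(n * f_n) / 100`, computed
  over percentages **as printed** (no renormalization when a row sums to
  99.9), reported to 2 decimals with ties rounded half away from zero. Both
  conventions are forced by reproduction of published rows: renormalizing a
  99.9-sum row shifts 2.75 to 2.76, and banker's rounding turns a computed
  1.165 into 1.16 rather than the reported 1.17.
- `percent_change()` — `round(100 * av / av_control)`, half away from zero,
  computed from **unrounded** averages (0.844/1.326 gives 64; using the
  rounded 0.84/1.33 would give 63).

### The ammonium-adduct fallback

An [M+NH4]+ adduct sits 17.0265 Da above the neutral mass. At charge 2 the
adduct's monoisotopic peak of the n-oxidized species lands
(17.0265 − 15.9949 − 1.0034)/2 ≈ 0.014 m/z away from the **+1 isotopic
peak** of the (n+1)-oxidized species — inside a 10 ppm window at
peptide-sized m/z. Summing four isotopic peaks then inflates the apparent
abundance of more-oxidized species. `detect_adduct_overlap()` flags exactly
the (n_ox, charge) pairs at risk from this three-constant arithmetic, and
`quantify_stoichiometry_monoiso()` implements the remedy: quantify from the
monoisotopic peaks only, which no adduct of a neighboring species can
reach. The `"auto"` mode of the workflow applies the fallback when the
geometry permits interference *and* adduct signal is actually present
(probed at the highest-oxidation species, whose adduct overlaps nothing).

Because all species in the 0..k family differ only by oxygen atoms, their
envelopes are nearly identical and the choice of 1 vs 4 summed peaks
cancels almost completely in the normalization; the residual difference (the ¹⁸O
contribution of the added oxygens) is below 0.1 percentage points for a
peptide of ~4 kDa, which is why both modes agree on adduct-free data.

## Site localization from b/y ions

`theoretical_fragments()` computes the complete singly charged b/y series;
a modification's mass is carried by exactly the fragments covering its
position, so positional isomers differ in the fragments that bracket their
sites. `localize()` enumerates all C(#Pro, n_ox) placements, scores each by
matched-fragment count (greedy nearest-match within a ppm tolerance, one
observed peak per theoretical ion), and returns the arg-max. Scoring is
intensity-blind by design — the minimal faithful rule when sites are
reported qualitatively — and ties are **surfaced** in `ambiguous_with`,
never broken silently: a spectrum containing only fragments that fail to
bracket two candidate prolines genuinely cannot distinguish them, and the
assignment object says so. Singly charged b/y ions without neutral losses
are an assumption of this module; multiply charged fragments and
probabilistic localization scores are out of scope.

## Internal-standard kinetics

Endpoint assays measure one stopped reaction per substrate concentration.
Quantification rests on a single stated assumption: the response of the
internal-standard peptide relative to the substrate equals its response
relative to the product. Under that assumption the product concentration
reduces to

> [P] = S0 · area_product / (area_substrate + area_product),

and the internal-standard-normalized form (product area over IS area,
scaled by the response factor calibrated from total analyte signal) is
algebraically identical; `product_concentration()` evaluates both and
asserts their agreement to 1e-9 as a consistency check. Velocities are
endpoint concentrations over reaction time (initial-rate regime: at the
measured vmax values over 20-30 min, conversion is a few percent of
substrate at the lowest concentration, so progress-curve curvature is
negligible). `fit_michaelis_menten()` runs Levenberg-Marquardt nonlinear
least squares on v = vmax·S/(Km+S), initialized from a Hanes-Woolf
linearization (S/v on S), which is better conditioned than a
Lineweaver-Burk start at sparse low-S designs; velocities are weighted
equally because no replicate structure exists in an endpoint design.
Standard errors come from the Jacobian at convergence.

A documented estimator diagnostic: when the lowest assayed concentration
sits far above Km, all observed velocities are near-saturated and Km is
weakly identified — the spread of recovered Km grows, and fits can collapse
to the boundary (reported as an error rather than a spurious estimate).
This matters when a low-Km enzyme (Km ≈ 8 uM) is assayed on a grid starting
at 22 uM: recovery remains accurate in the median but individual fits are
noticeably more variable than for mid-range Km values.

## Position-specific motifs

Hydroxylation context is summarized over a 5-residue window, offsets −1..+3
around the modified proline (the window length used both in earlier
substrate-requirement work and in the site-preference analysis this package
mirrors). `derive_motif()` pools the windows of all confirmed sites and
takes the **union** of observed residues per offset — sets, not frequency
weights, because the reported motifs are sets. Sites whose window crosses a
terminus are excluded from derivation and reported. `match_motif()` scans a
candidate sequence strictly (windows past a terminus never match).
Serialization uses the bracket notation `[STP]-P-[STP]-[TP]-[SP]`, and the
parser accepts `Pro` for the anchor.

On the IgA1 hinge peptide with positive sites {9,10,12,14,17,18,20}, the
union consensus is `[PST]-P-[PST]-[PT]-[PS]`. The corresponding published
motif carries an additional V in the −1 set; matching that V-containing
motif flags P6 (context V-P-S-T-P) even though P6 is reported as never
oxidized. No IgA1 positive site has V at −1, so the V cannot be derived
from these sites; the package reproduces the discrepancy and documents it
rather than patching either side.

## The synthetic-data generator

`simulate_lcms_run()` emulates the features of a centroided Q-TOF MS1 run
that the quantification actually consumes: species at theoretical m/z for
each (oxidation count, charge, adduct state, isotope peak), Gaussian
elution profiles whose integrated areas are proportional to stoichiometric
fraction × charge weight, and multiplicative lognormal noise (unit mean,
configured CV) on every centroid. Defaults encode the measurement
conditions being emulated: charge weights {2+: 0.7, 3+: 0.3} (doubly and
triply charged ions dominate the spectra), 10 ppm instrument tolerance (a
plausible Q-TOF value, configurable — no tolerance is stated for the
original instrument), Gaussian peak shape (the simplest shape preserving
area proportionality, which is all the trapezoidal integrator uses; no
exponentially modified tails), retention-time spacing of 0.25 min between
species with sigma 0.02 min, and 10 emitted isotope peaks (>99.9% envelope
coverage). When adducts are enabled, the generator self-checks that the
adduct/+1-isotope interference geometry holds at charge 2 and records the
result. The generator does **not** emulate profile-mode peaks, resolution-
dependent peak merging, isotope-dependent ionization efficiency, in-source
fragmentation, or ion mobility; recovery results on synthetic data
therefore validate the quantification arithmetic and the adduct fallback
logic, not detector physics.

`simulate_msms()` emits the complete singly charged b/y series at uniform
base intensity with multiplicative noise — sufficient because localization
scoring uses fragment presence, not intensity. `simulate_kinetics()`
generates endpoint assays from the Michaelis-Menten model with shared
substrate/product response factors; its default substrate grid is 8
log-spaced points over 22-5610 uM, the assayed concentration range. All
three generators are deterministic in (configuration, seed).

## Numerical choices

- Rounding of reported statistics: half away from zero, with a 1e-9 guard
  so decimal inputs represented inexactly in binary still round as a human
  reading the decimal would.
- EIC integration: trapezoid over the full trace by default; windows are
  configurable but unnecessary for well-separated synthetic peaks.
- Noise model: lognormal with unit mean (`sdlog² = log(1+cv²)`), so
  noiseless identities hold exactly at cv = 0 and areas remain unbiased.
- Fit initialization: Hanes-Woolf estimates; guarded fallbacks (max v,
  median S) when the linearization degenerates; final estimates always
  from nonlinear least squares with positivity bounds.
- Tie-breaking in localization: none — ties are reported.
- Degenerate inputs error early and descriptively (empty quantification,
  inverted windows, non-positive charges, all-equal substrate grids).

## Problem sizes used in the test suite

The shipped tests validate: stoichiometry recovery on the 7-species hinge
peptide mixture (noiseless, and 20 noisy seeds at 2% CV with 20% adduct
signal); site localization round-trips over every single-site placement on
the four substrate peptides; kinetics recovery for the four enzyme
parameter pairs (noiseless) and 100-seed median-Km recovery at 2% noise for
the two high-affinity scenarios; and property sweeps (mass additivity,
envelope-oracle equivalence, digest reconstruction, motif-scan
equivalence) over dozens of randomized cases at fixed seeds. These sizes
were chosen to estimate the relevant medians and means stably while keeping
the full suite in the tens of seconds.

## Known limitations

- Stoichiometry assumes equal ionization efficiency across the 0..k
  oxidation family; the method measures relative, not absolute, abundances.
- Overlapping envelopes are handled by the monoisotopic fallback, not by
  deconvolution.
- Site coordinates are peptide-local (1-based); mapping onto full-protein
  numbering is the caller's responsibility, since constructs differ.
- Glycoforms: a pentose (+132.0423 Da) on Hyp is representable as an EIC
  target, but glycoform statistics are out of scope.
- Kinetics covers single-substrate Michaelis-Menten without cosubstrate
  (2-oxoglutarate/O2) dependence or inhibition terms.
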