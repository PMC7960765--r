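# hyproquant

Quantitative analysis of peptidyl-proline 4-hydroxylation from LC-ESI-MS
data, for protein scientists and plant-biotechnology groups characterizing
prolyl 4-hydroxylase (P4H) activity on peptide substrates — e.g. the
proline-rich IgA1 hinge region produced in *Nicotiana benthamiana*, where
hydroxyproline (Hyp) is an unwanted, plant-specific modification that
anchors arabinose O-glycans.

The package covers the three measurable layers of the problem:

- **Stoichiometry** — the relative abundance of species with 0..k
  hydroxyprolines, from extracted ion chromatograms (EICs). For each
  oxidation count *n*, the abundance is the summed, integrated EIC area of
  the **first four isotopic peaks over all observed charge states** at the
  species' theoretical m/z (each oxidation adds 15.9949 Da, i.e. 16 / 8 /
  5.3 m/z units at charges 1/2/3), normalized to 100%. Derived statistics:
  the average Hyp count `sum(n·f_n)/100` and the percent change versus a
  control. When ammonium adducts ([M+NH4]+, +17.03 Da) contaminate the
  isotope pattern — the adduct of the *n*-ox species falls
  (17.0265−15.9949−1.0034)/z from the +1 isotope peak of the (*n*+1)-ox
  species — a **monoisotopic-only** fallback quantifies from the first
  isotopic peaks alone.
- **Site localization** — positional isomers are distinguished by singly
  charged b/y fragment ions: all C(#Pro, n) placements are enumerated and
  scored by matched-fragment count; ties are reported, never broken
  silently.
- **Kinetics** — internal-standard endpoint assays are converted to product
  concentrations via the shared-response-factor rule
  `[P] = S0·A_P/(A_S+A_P)`, then `v = [P]/t` is fitted with nonlinear least
  squares to the Michaelis–Menten law `v = vmax·S/(Km+S)` (Hanes–Woolf
  initialization, Levenberg–Marquardt refinement).

A **synthetic-data generator** produces ground-truthed centroided MS1 runs
(isotope envelopes, 2+/3+ charge states, optional ammonium adducts,
Gaussian elution, multiplicative noise), MS/MS spectra and kinetics assays,
so every stage is testable without instrument data. Position-specific
hydroxylation **motifs** (union consensus over −1..+3 windows, bracket
notation like `[STP]-P-[STP]-[TP]-[SP]`) round out the toolkit.

## Worked example

Simulate an adduct-contaminated run of the tryptic IgA1 hinge peptide with
a known Hyp stoichiometry, then quantify it both ways:

```r
library(hyproquant)
hinge <- SUBSTRATE_PEPTIDES[["IgA1HingeTryptic"]]

# protonated monoisotopic mass of the carbamidomethylated hinge peptide
mz(monoisotopic_mass(carbamidomethylate(hinge)), 1)
#> 4136.8899

f <- c(0.263, 0.279, 0.239, 0.160, 0.048, 0.011, 0.001); f <- f / sum(f)
truth <- ground_truth(hinge, f, adduct_fraction = 0.2, noise_cv = 0.02, seed = 1)
scans <- simulate_lcms_run(truth)

quantify_stoichiometry(scans, hinge, max_ox = 6)          # standard 4-peak mode
#> <hyp_distribution> HYTNPSQDVTVPCPVPSTPPTPSPSTPPTPSPSCCHPR
#>   %Hyp(0..6): 22.3 27.7 24.5 17.2 6.5 1.7 0.3
#>   av. #Hyp: 1.64

quantify_stoichiometry_monoiso(scans, hinge, max_ox = 6)  # adduct fallback
#> <hyp_distribution> HYTNPSQDVTVPCPVPSTPPTPSPSTPPTPSPSCCHPR
#>   %Hyp(0..6): 26.3 28.0 23.9 15.8 4.7 1.1 0.1
#>   av. #Hyp: 1.48
```

With 20% of each species' signal diverted into its ammonium adduct, the
4-peak quantification overestimates the higher-oxidized species (average
Hyp 1.64 against the true 1.49), because each species' adduct lands in the
window of the next species' second isotopic peak. The monoisotopic-only
fallback recovers the configured distribution to within a few tenths of a
percentage point. `detect_adduct_overlap(hinge, 6)` lists exactly which
(n_ox, charge) pairs are at risk at a given ppm tolerance.

Site localization and kinetics round-trip the same way:

```r
iga <- SUBSTRATE_PEPTIDES[["IgA1"]]
pf <- peptidoform(iga, mods = data.frame(position = 18, modification = "oxidation"))
localize(simulate_msms(pf), iga, n_ox = 1)
#> <site_assignment> VTVPVPSTPPTPSPSTPPTPSPS  n_ox=1  sites={18}  score=44

assay <- simulate_kinetics(km = 66, vmax = 0.02, reaction_time = 20,
                           noise_cv = 0.02, seed = 1)
fit_assay(assay)
#> <kinetic_parameters> Km = 62.73 uM (SE 3.4), vmax = 0.01972 uM/min (SE 0.000211)

derive_motif(c(IgA1 = iga), list(c(9, 10, 12, 14, 17, 18, 20)))
#> <positional_motif> [PST]-P-[PST]-[PT]-[PS]
```

The localization score is the number of matched b/y ions (44 = the full
2·(23−1) series); the kinetics fit recovers the generating parameters
(Km 66 uM, vmax 0.02 uM/min) to within the noise-limited uncertainty; and
the union consensus over the seven confirmed IgA1 sites yields the
5-position hydroxylation motif.

End-to-end workflows (`run_quantification_workflow()`,
`run_kinetics_workflow()`) batch these steps over conditions/enzymes and
emit report tables with provenance (config hash, seed, package version).
A thin command-line front end with `simulate` / `quantify` / `localize` /
`kinetics` / `motif` verbs is shipped at `inst/scripts/hyproquant.R`.

See the vignette `vignettes/hydroxyproline-analysis.Rmd` for the models,
assumptions, parameter defaults and limitations.

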