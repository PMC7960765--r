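Package: hyproquant
Title: Hydroxyproline Stoichiometry, Site Localization and Kinetics from LC-ESI-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying peptidyl-proline 4-hydroxylation by LC-ESI-MS.
    Computes peptide elemental compositions, monoisotopic masses and aggregated
    isotope envelopes; performs in-silico tryptic digestion and enumeration of
    oxidized peptidoforms; extracts ion chromatograms from centroided MS1 scans
    and quantifies the relative abundance of 0..k-times hydroxylated species by
    summed isotopic peak areas, with a monoisotopic-only fallback for runs
    contaminated by ammonium adducts; localizes hydroxylation sites from b/y
    fragment ions in MS/MS spectra; fits Michaelis-Menten parameters to
    internal-standard endpoint assays; and derives and matches position-specific
    hydroxylation sequence motifs. Ships a synthetic-data generator emulating
    Q-TOF LC-ESI-MS runs, MS/MS spectra and kinetics assays with full ground
    truth, so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
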