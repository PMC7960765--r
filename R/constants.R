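# Physical constants and residue chemistry.
#
# Monoisotopic atomic masses and natural isotope abundances from the standard
# IUPAC/CODATA compilations, documented to the precision the envelope and m/z
# arithmetic needs. A single authority table avoids mixed conventions between
# mass and abundance computations.

#' Mass of a proton in Da
#' @export
PROTON_MASS <- 1.007276467

#' Nominal isotope peak spacing in Da (13C - 12C mass difference)
#'
#' Aggregated isotope envelopes place the peak at nominal offset j at
#' `j * ISOTOPE_SPACING` above the monoisotopic mass.
#' @export
ISOTOPE_SPACING <- 1.0033548378

#' m/z shift of the ammonium adduct relative to the protonated species (Da)
#'
#' \[M+NH4\]+ sits NH3 (17.026549 Da) above \[M+H\]+ at charge 1;
#' divide by the charge for multiply charged ions.
#' @export
AMMONIUM_ADDUCT_SHIFT <- 17.026549

# monoisotopic mass of the lightest isotope, per element
.ATOMIC_MASSES <- c(
  H = 1.007825032,
  C = 12.000000000,
  N = 14.003074005,
  O = 15.994914620,
  S = 31.972071174
)

WATER_MASS <- 2 * .ATOMIC_MASSES[["H"]] + .ATOMIC_MASSES[["O"]]

# isotope patterns indexed by nominal offset from the lightest isotope
# (offset = mass number - lightest mass number); abundances sum to 1
.ISOTOPE_PATTERNS <- list(
  H = c(0.999885, 0.000115),
  C = c(0.9893, 0.0107),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001)
)

#' Element isotope table
#'
#' Machine-readable table of the isotope masses and natural abundances used by
#' every mass and envelope computation in the package.
#'
#' @return A data.frame with columns `element`, `nominal_offset` (0 for the
#'   lightest isotope), `mass` (Da) and `abundance` (unit fraction; abundances
#'   of an element sum to 1).
#' @examples
#' isotope_table()
#' @export
isotope_table <- function() {
  rows <- lapply(names(.ISOTOPE_PATTERNS), function(el) {
    ab <- .ISOTOPE_PATTERNS[[el]]
    data.frame(
      element = el,
      nominal_offset = seq_along(ab) - 1L,
      mass = .ATOMIC_MASSES[[el]] + (seq_along(ab) - 1L) * ISOTOPE_SPACING,
      abundance = ab
    )
  })
  out <- do.call(rbind, rows)
  out[out$abundance > 0, , drop = FALSE]
}

# residue (i.e. dehydrated amino acid) elemental compositions, C/H/N/O/S
.RESIDUE_COMPOSITIONS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

#' Built-in peptide modifications
#'
#' The two modifications of the hydroxylation workflow: `oxidation`
#' (+15.994915 Da, +O; proline to 4-hydroxyproline) and `carbamidomethyl`
#' (+57.021464 Da, +C2H3NO; iodoacetamide-alkylated cysteine). A modification
#' is a list with `name`, `mass_shift` (Da, monoisotopic), `composition_delta`
#' (named integer vector) and `allowed_residues`.
#'
#' @format A named list of modification definitions.
#' @export
MODIFICATIONS <- list(
  oxidation = list(
    name = "oxidation",
    mass_shift = 15.994915,
    composition_delta = c(O = 1),
    allowed_residues = "P"
  ),
  carbamidomethyl = list(
    name = "carbamidomethyl",
    mass_shift = 57.021464,
    composition_delta = c(C = 2, H = 3, N = 1, O = 1),
    allowed_residues = "C"
  )
)

#' Peptide substrates used in the hydroxylation assays
#'
#' Named character vector of the four synthetic P4H substrate peptides (the
#' proline-rich IgA1 hinge region, an EPO O-glycosylation region peptide, the
#' Art v 1 C-terminal extensin-like region and an Arabidopsis STRUBBELIG
#' peptide), the internal-standard peptide used for kinetics, and the tryptic
#' IgA1 hinge-region peptide monitored in planta.
#' @export
SUBSTRATE_PEPTIDES <- c(
  IgA1       = "VTVPVPSTPPTPSPSTPPTPSPS",
  EPO        = "AQKEAISPPDAASAA",
  ArtV1      = "AAGGSPSPPADGGSPPPPADG",
  STRUBBELIG = "DGTPFNTSIITPPPPPCCDPPPATHR",
  InternalStandard = "PTTTPITTTTTVTPTPTPTGTQTK",
  IgA1HingeTryptic = "HYTNPSQDVTVPCPVPSTPPTPSPSTPPTPSPSCCHPR"
)
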