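# EIC extraction and relative quantification of hydroxyproline stoichiometry:
# summed areas of the first four isotopic peaks over all observed charge
# states, with a monoisotopic-only fallback when ammonium adducts contaminate
# the isotope pattern.

#' Extract an ion chromatogram
#'
#' Per scan, sums the intensities of all peaks within the ppm window around
#' the target m/z; scans with no peak in the window contribute zero.
#'
#' @param scans A [scan_set].
#' @param target_mz Target m/z.
#' @param tolerance_ppm Window half-width in ppm (> 0).
#' @return An `eic`: data.frame with columns `rt` and `intensity`, plus
#'   attributes `target_mz` and `tolerance_ppm`.
#' @export
extract_eic <- function(scans, target_mz, tolerance_ppm = scans$mz_tolerance_ppm) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  win <- target_mz * tolerance_ppm * 1e-6
  intensity <- vapply(scans$scans, function(s) {
    if (!nrow(s$peaks)) return(0)
    sum(s$peaks$intensity[abs(s$peaks$mz - target_mz) <= win])
  }, numeric(1))
  structure(
    data.frame(rt = vapply(scans$scans, function(s) s$rt, numeric(1)),
               intensity = intensity),
    class = c("eic", "data.frame"),
    target_mz = target_mz, tolerance_ppm = tolerance_ppm
  )
}

#' Integrate an EIC peak
#'
#' Trapezoidal integral of the trace over a retention-time window.
#'
#' @param eic An [extract_eic] trace.
#' @param rt_window c(min, max) in minutes; default the full trace.
#' @return Non-negative area.
#' @export
integrate_peak <- function(eic, rt_window = range(eic$rt)) {
  if (rt_window[1] > rt_window[2]) stop("inverted rt window")
  keep <- eic$rt >= rt_window[1] & eic$rt <= rt_window[2]
  rt <- eic$rt[keep]; y <- eic$intensity[keep]
  if (length(rt) < 2) return(0)
  sum(diff(rt) * (head(y, -1) + y[-1]) / 2)
}

# summed EIC area of one species over charges and isotope peaks
.species_area <- function(scans, neutral_mass, charges, n_iso, tolerance_ppm,
                          adduct_shift = 0) {
  total <- 0
  for (z in charges) {
    base <- mz(neutral_mass, z, adduct_shift)
    for (j in seq_len(n_iso) - 1L) {
      eic <- extract_eic(scans, base + j * ISOTOPE_SPACING / z, tolerance_ppm)
      total <- total + integrate_peak(eic)
    }
  }
  total
}

#' Quantify hydroxylation stoichiometry from an MS1 run
#'
#' For each oxidation count n in 0..`max_ox`, sums the integrated EIC areas of
#' the first `n_iso` isotopic peaks over all given charge states at the
#' species' theoretical m/z values, and normalizes the per-species abundances
#' to 100%. Cysteines are treated as carbamidomethylated.
#'
#' @param scans A [scan_set].
#' @param peptide Peptide sequence.
#' @param max_ox Highest oxidation count to consider (<= number of Pro).
#' @param charges Integer charge states to sum over.
#' @param n_iso Number of isotopic peaks summed per charge state (default 4,
#'   the standard workflow; 1 gives the monoisotopic-only fallback).
#' @param tolerance_ppm EIC window half-width in ppm.
#' @param control Optional control [hyp_distribution] (or its raw average Hyp
#'   count) against which the percent change is computed.
#' @return A [hyp_distribution].
#' @export
quantify_stoichiometry <- function(scans, peptide, max_ox,
                                   charges = c(2L, 3L), n_iso = 4L,
                                   tolerance_ppm = scans$mz_tolerance_ppm,
                                   control = NULL) {
  if (max_ox > length(proline_sites(peptide)))
    stop("max_ox exceeds the number of prolines in the peptide")
  base_mass <- monoisotopic_mass(carbamidomethylate(peptide))
  abundances <- vapply(0:max_ox, function(n) {
    .species_area(scans, base_mass + n * MODIFICATIONS$oxidation$mass_shift,
                  charges, n_iso, tolerance_ppm)
  }, numeric(1))
  if (sum(abundances) <= 0)
    stop("empty quantification: no signal for any species")
  hyp_distribution(peptide, 100 * abundances / sum(abundances),
                   control = control)
}

#' Monoisotopic-only stoichiometry quantification
#'
#' The fallback used when ammonium adducts contaminate the isotope pattern:
#' identical to [quantify_stoichiometry] but summing exclusively the
#' monoisotopic peaks of all observed charge states.
#'
#' @inheritParams quantify_stoichiometry
#' @return A [hyp_distribution].
#' @export
quantify_stoichiometry_monoiso <- function(scans, peptide, max_ox,
                                           charges = c(2L, 3L),
                                           tolerance_ppm = scans$mz_tolerance_ppm,
                                           control = NULL) {
  quantify_stoichiometry(scans, peptide, max_ox, charges, n_iso = 1L,
                         tolerance_ppm = tolerance_ppm, control = control)
}

#' Detect ammonium-adduct interference
#'
#' Flags every (oxidation count, charge) species whose +1 isotopic peak lies
#' within the m/z tolerance of the ammonium-adduct monoisotopic peak of the
#' species with one oxidation fewer — the geometry under which a +17 Da adduct
#' adds to the intensity of the second isotopic peak.
#'
#' @param peptide Peptide sequence (Cys carbamidomethylated).
#' @param max_ox Highest oxidation count considered.
#' @param charges Integer charge states.
#' @param tolerance_ppm m/z tolerance in ppm.
#' @return data.frame of at-risk species: columns `n_ox`, `charge`,
#'   `delta_mz` (separation between the interfering peaks, m/z units).
#' @export
detect_adduct_overlap <- function(peptide, max_ox, charges = c(2L, 3L),
                                  tolerance_ppm = 10) {
  base_mass <- monoisotopic_mass(carbamidomethylate(peptide))
  rows <- list()
  for (n in seq_len(max_ox)) {  # species n contaminated by adduct of n-1
    m_lo <- base_mass + (n - 1) * MODIFICATIONS$oxidation$mass_shift
    m_hi <- m_lo + MODIFICATIONS$oxidation$mass_shift
    for (z in charges) {
      mz_adduct <- mz(m_lo, z, AMMONIUM_ADDUCT_SHIFT)
      mz_plus1 <- mz(m_hi, z) + ISOTOPE_SPACING / z
      delta <- abs(mz_adduct - mz_plus1)
      if (delta <= mz_plus1 * tolerance_ppm * 1e-6)
        rows[[length(rows) + 1L]] <-
          data.frame(n_ox = n, charge = z, delta_mz = delta)
    }
  }
  if (!length(rows))
    return(data.frame(n_ox = integer(), charge = integer(),
                      delta_mz = numeric()))
  do.call(rbind, rows)
}

#' Hydroxyproline stoichiometry distribution
#'
#' Container for the relative abundances of species with 0..k hydroxyprolines
#' on one peptide, with the derived statistics: the average Hyp count and,
#' when a control is supplied, the percent change versus that control.
#'
#' @param peptide Peptide sequence.
#' @param fractions_percent Numeric vector `f_0..f_k` in percent.
#' @param control Optional control `hyp_distribution` (or a raw average Hyp
#'   count) for the percent-change column.
#' @return A `hyp_distribution` object: list with `peptide`,
#'   `fractions_percent`, `average_hyp` (2 decimals, half away from zero),
#'   `average_hyp_raw` (unrounded) and `percent_change` (integer or NA).
#' @export
hyp_distribution <- function(peptide, fractions_percent, control = NULL) {
  if (any(fractions_percent < 0)) stop("fractions must be non-negative")
  raw <- sum((seq_along(fractions_percent) - 1) * fractions_percent) / 100
  pc <- NA_integer_
  if (!is.null(control)) {
    ctrl_raw <- if (inherits(control, "hyp_distribution"))
      control$average_hyp_raw else as.numeric(control)
    pc <- percent_change(raw, ctrl_raw)
  }
  structure(list(
    peptide = peptide,
    fractions_percent = fractions_percent,
    average_hyp = round_half_away(raw, 2),
    average_hyp_raw = raw,
    percent_change = pc
  ), class = "hyp_distribution")
}

#' @export
print.hyp_distribution <- function(x, ...) {
  cat("<hyp_distribution> ", x$peptide, "\n", sep = "")
  f <- sprintf("%.1f", x$fractions_percent)
  cat("  %Hyp(0..", length(f) - 1, "): ", paste(f, collapse = " "), "\n", sep = "")
  cat(sprintf("  av. #Hyp: %.2f", x$average_hyp))
  if (!is.na(x$percent_change))
    cat(sprintf("   %% change: %d", x$percent_change))
  cat("\n")
  invisible(x)
}

#' Round half away from zero
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded value. Values within 1e-9 of a half-way point round away
#'   from zero, which also guards against binary representation error in
#'   decimal inputs.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Average hydroxyproline count of a printed distribution
#'
#' `sum(n * f_n) / 100` over percentages as printed: the input is NOT
#' renormalized even when it sums to 99.9 or 100.1. Reported to 2 decimals,
#' rounding half away from zero.
#'
#' @param fractions_percent Percentages `f_0..f_k`.
#' @return Average Hyp count, 2 decimals.
#' @examples
#' average_hyp(c(26.3, 27.9, 23.9, 16.0, 4.8, 1.1, 0.1))  # 1.49
#' @export
average_hyp <- function(fractions_percent) {
  if (any(fractions_percent < 0)) stop("fractions must be non-negative")
  round_half_away(
    sum((seq_along(fractions_percent) - 1) * fractions_percent) / 100, 2)
}

#' Percent change of an average Hyp count versus a control
#'
#' `round(100 * av / av_control)` to the nearest integer, half away from
#' zero. Computed from unrounded averages when reproducing reported tables.
#'
#' @param av Average Hyp count.
#' @param av_control Control average Hyp count (> 0).
#' @return Integer percent.
#' @export
percent_change <- function(av, av_control) {
  if (av_control <= 0) stop("control average must be > 0")
  as.integer(round_half_away(100 * av / av_control, 0))
}
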