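# Hydroxylation site localization from MS/MS fragment spectra: theoretical
# singly charged b/y ions, spectrum matching, and exhaustive positional-isomer
# scoring with explicit ambiguity reporting.

# per-residue masses including positioned modifications
.residue_masses <- function(pf) {
  residues <- strsplit(pf$sequence, "")[[1]]
  masses <- vapply(residues, function(r)
    sum(.RESIDUE_COMPOSITIONS[[r]] * .ATOMIC_MASSES[names(.RESIDUE_COMPOSITIONS[[r]])]),
    numeric(1))
  if (nrow(pf$mods))
    masses[pf$mods$position] <- masses[pf$mods$position] +
      vapply(pf$mods$modification, function(m) MODIFICATIONS[[m]]$mass_shift,
             numeric(1))
  unname(masses)
}

#' Theoretical b/y fragment ions of a peptidoform
#'
#' Singly charged b- and y-series: `b_i = sum(first i residue+mod masses) +
#' proton`, `y_j = sum(last j residue+mod masses) + water + proton`. A
#' modification's mass is carried by exactly the fragments covering its
#' position.
#'
#' @param pf Peptidoform (or sequence string) of length >= 2.
#' @return data.frame with columns `series` ("b"/"y"), `index` (1..L-1),
#'   `mz`, `cover_start`, `cover_end` (residue positions the fragment spans);
#'   2(L-1) rows.
#' @export
theoretical_fragments <- function(pf) {
  pf <- as_peptidoform(pf)
  L <- nchar(pf$sequence)
  if (L < 2) stop("peptide must have at least 2 residues")
  masses <- .residue_masses(pf)
  idx <- seq_len(L - 1L)
  b_mz <- cumsum(masses)[idx] + PROTON_MASS
  y_mz <- rev(cumsum(rev(masses)))[L - idx + 1L] + WATER_MASS + PROTON_MASS
  rbind(
    data.frame(series = "b", index = idx, mz = b_mz,
               cover_start = 1L, cover_end = idx),
    data.frame(series = "y", index = idx, mz = y_mz,
               cover_start = L - idx + 1L, cover_end = L)
  )
}

#' Match an observed peak list against theoretical fragments
#'
#' Greedy nearest-match within a ppm tolerance: candidate pairs are ranked by
#' absolute ppm error and accepted one at a time, so each observed peak
#' matches at most one theoretical ion and vice versa.
#'
#' @param observed data.frame with columns `mz` (and optionally `intensity`).
#' @param theoretical Output of [theoretical_fragments].
#' @param tolerance_ppm Match tolerance in ppm (> 0).
#' @return The matched subset of `theoretical` with extra columns
#'   `observed_mz` and `ppm_error`.
#' @export
match_spectrum <- function(observed, theoretical, tolerance_ppm = 10) {
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0")
  if (!nrow(observed) || !nrow(theoretical))
    return(cbind(theoretical[integer(), , drop = FALSE],
                 observed_mz = numeric(), ppm_error = numeric()))
  pairs <- expand.grid(ti = seq_len(nrow(theoretical)),
                       oi = seq_len(nrow(observed)))
  pairs$ppm <- (observed$mz[pairs$oi] - theoretical$mz[pairs$ti]) /
    theoretical$mz[pairs$ti] * 1e6
  pairs <- pairs[abs(pairs$ppm) <= tolerance_ppm, , drop = FALSE]
  pairs <- pairs[order(abs(pairs$ppm)), , drop = FALSE]
  used_t <- logical(nrow(theoretical)); used_o <- logical(nrow(observed))
  keep <- integer()
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs$ti[r]; oi <- pairs$oi[r]
    if (!used_t[ti] && !used_o[oi]) {
      used_t[ti] <- TRUE; used_o[oi] <- TRUE
      keep <- c(keep, r)
    }
  }
  sel <- pairs[keep, , drop = FALSE]
  out <- theoretical[sel$ti, , drop = FALSE]
  out$observed_mz <- observed$mz[sel$oi]
  out$ppm_error <- sel$ppm
  out[order(out$series, out$index), , drop = FALSE]
}

#' Localize hydroxylation sites from an MS/MS spectrum
#'
#' Enumerates all placements of `n_ox` oxidations on the peptide's prolines,
#' scores each positional isomer by its matched-fragment count against the
#' observed spectrum, and returns the best-scoring site set. Placements tying
#' with the best score are reported in `ambiguous_with` — ties are surfaced,
#' never broken silently.
#'
#' @param observed Peak list data.frame (`mz`, `intensity`) or a spectrum as
#'   returned by [read_mgf]/[simulate_msms].
#' @param peptide Peptide sequence; cysteines are carbamidomethylated before
#'   fragment computation.
#' @param n_ox Number of oxidations to place (<= number of Pro).
#' @param tolerance_ppm Fragment match tolerance in ppm.
#' @return A `site_assignment`: list with `peptide`, `n_ox`, `sites` (integer
#'   positions), `score` (matched-fragment count), `ambiguous_with` (list of
#'   equally scoring site sets, empty when unambiguous) and `scores` (the full
#'   per-placement score table).
#' @export
localize <- function(observed, peptide, n_ox, tolerance_ppm = 10) {
  if (is.list(observed) && !is.data.frame(observed) && !is.null(observed$peaks))
    observed <- observed$peaks
  sites_all <- proline_sites(peptide)
  if (n_ox > length(sites_all))
    stop("n_ox exceeds the number of prolines in the peptide")
  forms <- enumerate_oxoforms(peptide, sites_all, n_ox, fixed_cam = TRUE)
  placements <- lapply(forms, function(pf)
    pf$mods$position[pf$mods$modification == "oxidation"])
  scores <- vapply(forms, function(pf)
    nrow(match_spectrum(observed, theoretical_fragments(pf), tolerance_ppm)),
    numeric(1))
  best <- max(scores)
  winners <- which(scores == best)
  score_table <- data.frame(
    sites = vapply(placements, function(s) paste(s, collapse = ","),
                   character(1)),
    score = scores
  )
  structure(list(
    peptide = peptide,
    n_ox = as.integer(n_ox),
    sites = placements[[winners[1]]],
    score = best,
    ambiguous_with = placements[winners[-1]],
    scores = score_table
  ), class = "site_assignment")
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("<site_assignment> %s  n_ox=%d  sites={%s}  score=%g\n",
              x$peptide, x$n_ox, paste(x$sites, collapse = ","), x$score))
  if (length(x$ambiguous_with))
    cat("  ambiguous with:",
        paste(vapply(x$ambiguous_with, function(s) paste(s, collapse = ","),
                     character(1)), collapse = " | "), "\n")
  invisible(x)
}
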