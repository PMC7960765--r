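# Peptide mass and composition arithmetic: peptidoforms, elemental
# compositions, monoisotopic masses, m/z, aggregated isotope envelopes,
# tryptic digestion and oxoform enumeration.

#' Create an elemental composition
#'
#' An elemental composition is a named integer vector of non-negative atom
#' counts. Addition and subtraction are element-wise; subtraction below zero
#' is an error.
#'
#' @param counts Named numeric vector (e.g. `c(C = 2, H = 5, N = 1, O = 2)`).
#' @return An `elemental_composition` object.
#' @export
elemental_composition <- function(counts = c()) {
  counts <- counts[counts != 0]
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("composition counts must be named by element symbol")
  if (any(counts < 0))
    stop("element counts must be non-negative")
  storage.mode(counts) <- "double"
  structure(counts, class = "elemental_composition")
}

#' @rdname elemental_composition
#' @param x,y Compositions (or named count vectors).
#' @param sign +1 to add, -1 to subtract.
#' @export
composition_add <- function(x, y, sign = 1) {
  els <- union(names(x), names(y))
  out <- vapply(els, function(el) {
    a <- if (el %in% names(x)) unclass(x)[[el]] else 0
    b <- if (el %in% names(y)) unclass(y)[[el]] else 0
    a + sign * b
  }, numeric(1))
  if (any(out < 0))
    stop("composition subtraction yields a negative count for ",
         paste(names(out)[out < 0], collapse = ", "))
  elemental_composition(out)
}

#' Construct a peptidoform
#'
#' A peptidoform is a peptide sequence over the 20-letter amino-acid alphabet
#' together with positioned modifications. Positions are 1-based residue
#' indices; at most one modification per position; the residue at each
#' modified position must be allowed by the modification (oxidation on Pro,
#' carbamidomethyl on Cys).
#'
#' @param sequence Peptide string.
#' @param mods Named list or data.frame of modifications: either a list of
#'   `list(position =, modification =)` entries or a data.frame with columns
#'   `position` and `modification` (modification names from [MODIFICATIONS]).
#' @return A `peptidoform` object (list with `sequence` and a data.frame
#'   `mods` of `position`, `modification`).
#' @examples
#' peptidoform("VTVPVPSTPPTPSPSTPPTPSPS",
#'             mods = data.frame(position = 18, modification = "oxidation"))
#' @export
peptidoform <- function(sequence, mods = NULL) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  residues <- strsplit(sequence, "")[[1]]
  bad <- which(!residues %in% names(.RESIDUE_COMPOSITIONS))
  if (length(bad))
    stop(sprintf("unknown residue '%s' at position %d", residues[bad[1]], bad[1]))
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), modification = character())
  } else if (is.list(mods) && !is.data.frame(mods)) {
    mods <- data.frame(
      position = vapply(mods, function(m) as.integer(m$position), integer(1)),
      modification = vapply(mods, function(m) m$modification, character(1))
    )
  }
  mods$position <- as.integer(mods$position)
  if (anyDuplicated(mods$position))
    stop("at most one modification per position")
  if (nrow(mods)) {
    if (any(mods$position < 1 | mods$position > length(residues)))
      stop("modification position outside the peptide")
    for (i in seq_len(nrow(mods))) {
      def <- MODIFICATIONS[[mods$modification[i]]]
      if (is.null(def)) stop("unknown modification: ", mods$modification[i])
      if (!residues[mods$position[i]] %in% def$allowed_residues)
        stop(sprintf("%s not allowed on residue %s at position %d",
                     def$name, residues[mods$position[i]], mods$position[i]))
    }
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
  }
  structure(list(sequence = sequence, mods = mods), class = "peptidoform")
}

#' @export
print.peptidoform <- function(x, ...) {
  lab <- if (nrow(x$mods)) {
    paste0(" [", paste(sprintf("%s@%d", x$mods$modification, x$mods$position),
                       collapse = ", "), "]")
  } else ""
  cat("<peptidoform> ", x$sequence, lab, "\n", sep = "")
  invisible(x)
}

# coerce a bare string to an unmodified peptidoform
as_peptidoform <- function(pf) {
  if (inherits(pf, "peptidoform")) pf else peptidoform(pf)
}

#' Apply carbamidomethyl to every cysteine
#'
#' Fixed-modification helper mirroring iodoacetamide alkylation during sample
#' preparation: all Cys residues carry carbamidomethyl.
#'
#' @param pf Peptidoform or sequence string.
#' @param extra_mods Optional extra mods data.frame (e.g. oxidations) merged in.
#' @return A peptidoform.
#' @export
carbamidomethylate <- function(pf, extra_mods = NULL) {
  pf <- as_peptidoform(pf)
  cys <- which(strsplit(pf$sequence, "")[[1]] == "C")
  mods <- rbind(
    pf$mods,
    if (length(cys)) data.frame(position = cys, modification = "carbamidomethyl"),
    extra_mods
  )
  peptidoform(pf$sequence, mods = unique(mods))
}

#' Elemental composition of a peptidoform
#'
#' Sum of the residue compositions, plus one water for the termini, plus the
#' composition deltas of all modifications.
#'
#' @param pf Peptidoform or sequence string.
#' @return An [elemental_composition].
#' @export
peptide_composition <- function(pf) {
  pf <- as_peptidoform(pf)
  residues <- strsplit(pf$sequence, "")[[1]]
  total <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # water
  for (r in residues) total <- total + .RESIDUE_COMPOSITIONS[[r]]
  comp <- elemental_composition(total)
  for (m in pf$mods$modification)
    comp <- composition_add(comp, MODIFICATIONS[[m]]$composition_delta)
  comp
}

#' Neutral monoisotopic mass of a peptidoform
#'
#' @param pf Peptidoform or sequence string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("PTTTPITTTTTVTPTPTPTGTQTK")
#' @export
monoisotopic_mass <- function(pf) {
  comp <- peptide_composition(pf)
  sum(unclass(comp) * .ATOMIC_MASSES[names(comp)])
}

#' m/z of an ion
#'
#' `(neutral_mass + charge * proton + adduct_shift) / charge`. The default is
#' pure protonation; pass `adduct_shift = AMMONIUM_ADDUCT_SHIFT` for the
#' \[M+NH4\]+ species.
#'
#' @param neutral_mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge.
#' @param adduct_shift Additional mass (Da) beyond protonation; default 0.
#' @return m/z.
#' @export
mz <- function(neutral_mass, charge, adduct_shift = 0) {
  if (any(charge <= 0) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (neutral_mass + charge * PROTON_MASS + adduct_shift) / charge
}

# discrete linear convolution of two abundance vectors
.convolve_patterns <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

# pattern of n identical atoms, by binary exponentiation of the element pattern
.element_power <- function(pattern, n, max_len) {
  result <- 1
  base <- pattern
  while (n > 0) {
    if (n %% 2 == 1) {
      result <- .convolve_patterns(result, base)
      if (length(result) > max_len) result <- result[seq_len(max_len)]
    }
    n <- n %/% 2
    if (n > 0) {
      base <- .convolve_patterns(base, base)
      if (length(base) > max_len) base <- base[seq_len(max_len)]
    }
  }
  result
}

#' Aggregated isotope envelope of a composition
#'
#' Computes the nominal-offset (unit-spaced) isotopic abundance pattern by
#' iterative convolution of the per-element isotope patterns, truncates it to
#' `n_peaks` peaks and renormalizes. Offset 0 is the monoisotopic peak.
#'
#' @param comp An [elemental_composition] (or named count vector), or a
#'   peptidoform/sequence, which is first converted via [peptide_composition].
#' @param n_peaks Number of peaks to keep (>= 1).
#' @return An `isotope_envelope`: data.frame with columns `offset` (0, 1, ...)
#'   and `abundance` (sums to 1).
#' @examples
#' isotope_distribution(c(C = 1), n_peaks = 2)
#' @export
isotope_distribution <- function(comp, n_peaks = 4L) {
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  if (is.character(comp) || inherits(comp, "peptidoform"))
    comp <- peptide_composition(comp)
  counts <- unclass(comp)
  if (!length(counts)) stop("empty composition")
  unknown <- setdiff(names(counts), names(.ISOTOPE_PATTERNS))
  if (length(unknown))
    stop("no isotope table for element: ", paste(unknown, collapse = ", "))
  # keep headroom beyond n_peaks so truncation error stays in renormalization
  max_len <- n_peaks + 8L
  env <- 1
  for (el in names(counts)) {
    env <- .convolve_patterns(
      env, .element_power(.ISOTOPE_PATTERNS[[el]], counts[[el]], max_len))
    if (length(env) > max_len) env <- env[seq_len(max_len)]
  }
  env <- env[seq_len(min(n_peaks, length(env)))]
  env <- env / sum(env)
  structure(
    data.frame(offset = seq_along(env) - 1L, abundance = env),
    class = c("isotope_envelope", "data.frame")
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the following residue is P. With
#' `missed_cleavages = m`, all unions of up to `m + 1` adjacent fragments are
#' returned as well.
#'
#' @param sequence Protein/peptide string.
#' @param missed_cleavages Non-negative integer.
#' @return data.frame with columns `peptide`, `start`, `end` (1-based,
#'   inclusive), `n_missed`; ordered by start position then length. The
#'   0-missed fragments concatenate to the input.
#' @examples
#' tryptic_digest("AKGR", missed_cleavages = 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (missed_cleavages < 0) stop("missed_cleavages must be >= 0")
  residues <- strsplit(sequence, "")[[1]]
  n <- length(residues)
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | residues[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n))
  starts <- head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  k <- length(starts)
  rows <- list()
  for (i in seq_len(k)) {
    for (m in 0:min(missed_cleavages, k - i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = substr(sequence, starts[i], ends[i + m]),
        start = starts[i], end = ends[i + m], n_missed = m
      )
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Proline positions of a peptide
#' @param sequence Peptide string.
#' @return Integer vector of 1-based Pro positions.
#' @export
proline_sites <- function(sequence) {
  which(strsplit(sequence, "")[[1]] == "P")
}

#' Enumerate positional isomers of n oxidations
#'
#' Returns every placement of `n_ox` oxidations on the candidate proline
#' sites, in deterministic lexicographic order of the site sets. Cysteines
#' are carbamidomethylated when `fixed_cam = TRUE`.
#'
#' @param sequence Peptide string.
#' @param candidate_sites 1-based positions, all prolines; defaults to every
#'   Pro in the sequence.
#' @param n_ox Number of oxidations, 0..length(candidate_sites).
#' @param fixed_cam Apply carbamidomethyl to all Cys (default FALSE).
#' @return List of peptidoforms, length `choose(length(candidate_sites), n_ox)`.
#' @export
enumerate_oxoforms <- function(sequence, candidate_sites = proline_sites(sequence),
                               n_ox, fixed_cam = FALSE) {
  residues <- strsplit(sequence, "")[[1]]
  if (any(residues[candidate_sites] != "P"))
    stop("candidate sites must all be proline residues")
  if (n_ox < 0 || n_ox > length(candidate_sites))
    stop("n_ox must be between 0 and the number of candidate sites")
  candidate_sites <- sort(as.integer(candidate_sites))
  placements <- if (n_ox == 0) list(integer()) else
    apply(utils::combn(candidate_sites, n_ox), 2, identity, simplify = FALSE)
  lapply(placements, function(sites) {
    mods <- if (length(sites))
      data.frame(position = sites, modification = "oxidation") else NULL
    if (fixed_cam) carbamidomethylate(sequence, extra_mods = mods)
    else peptidoform(sequence, mods = mods)
  })
}
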