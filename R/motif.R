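# Position-specific hydroxylation motifs: extraction of residue windows
# around modified prolines, union consensus, matching against candidate
# sequences, and the bracket text serialization.

#' Construct a positional motif
#'
#' A positional motif is an ordered list of allowed-residue sets over a window
#' of offsets relative to the modified proline (the anchor, offset 0, is
#' always `{P}`).
#'
#' @param allowed List of character vectors, one per offset, covering the
#'   window in order; each set non-empty.
#' @param window c(start_offset, end_offset) relative to the anchor; must
#'   cover offset 0. Default -1..+3 (the 5-residue hydroxylation context).
#' @return A `positional_motif`.
#' @export
positional_motif <- function(allowed, window = c(-1L, 3L)) {
  offsets <- seq.int(window[1], window[2])
  if (!0 %in% offsets) stop("window must cover the anchor (offset 0)")
  if (length(allowed) != length(offsets))
    stop("need one allowed-residue set per window offset")
  if (any(vapply(allowed, length, integer(1)) == 0))
    stop("allowed-residue sets must be non-empty")
  allowed <- lapply(allowed, function(s) sort(unique(s)))
  anchor <- which(offsets == 0)
  if (!identical(allowed[[anchor]], "P"))
    stop("anchor set must be exactly {P}")
  structure(list(allowed = allowed, window = as.integer(window),
                 offsets = offsets),
            class = "positional_motif")
}

#' @export
print.positional_motif <- function(x, ...) {
  cat("<positional_motif> ", format_motif(x), "\n", sep = "")
  invisible(x)
}

#' Extract residue windows around hydroxylation sites
#'
#' One window per site whose full extent lies inside the sequence; sites too
#' close to a terminus are skipped and reported in the `"skipped"` attribute.
#'
#' @param sequence Peptide string.
#' @param sites 1-based positions of modified prolines.
#' @param window c(start_offset, end_offset); default -1..+3.
#' @return Character matrix, one row per usable site (rownames = site
#'   positions), one column per offset; attribute `"skipped"` lists the
#'   omitted sites.
#' @export
extract_windows <- function(sequence, sites, window = c(-1L, 3L)) {
  residues <- strsplit(sequence, "")[[1]]
  if (any(residues[sites] != "P"))
    stop("all sites must be proline residues")
  offsets <- seq.int(window[1], window[2])
  ok <- sites + window[1] >= 1 & sites + window[2] <= length(residues)
  rows <- t(vapply(sites[ok], function(s) residues[s + offsets],
                   character(length(offsets))))
  if (!length(sites[ok]))
    rows <- matrix(character(), ncol = length(offsets))
  rownames(rows) <- sites[ok]
  colnames(rows) <- offsets
  structure(rows, skipped = sites[!ok])
}

#' Union consensus motif over site windows
#'
#' The allowed set at each offset is the union of the residues observed there
#' across all windows; the anchor is forced to `{P}`.
#'
#' @param windows Character matrix from [extract_windows] (>= 1 row).
#' @param window c(start_offset, end_offset) the matrix covers.
#' @return A [positional_motif].
#' @export
consensus_motif <- function(windows, window = c(-1L, 3L)) {
  if (!nrow(windows)) stop("need at least one site window")
  offsets <- seq.int(window[1], window[2])
  allowed <- lapply(seq_along(offsets), function(j)
    sort(unique(windows[, j])))
  allowed[[which(offsets == 0)]] <- "P"
  positional_motif(allowed, window)
}

#' Match a motif against a sequence
#'
#' Returns every anchor position whose surrounding residues each belong to
#' the corresponding allowed set. Windows extending past a terminus never
#' match (strict boundary handling).
#'
#' @param motif A [positional_motif].
#' @param sequence Candidate peptide/protein string.
#' @return Integer vector of matching anchor positions (empty when none).
#' @export
match_motif <- function(motif, sequence) {
  residues <- strsplit(sequence, "")[[1]]
  n <- length(residues)
  anchors <- seq_len(n)
  anchors <- anchors[anchors + motif$window[1] >= 1 &
                     anchors + motif$window[2] <= n]
  hits <- vapply(anchors, function(p)
    all(mapply(function(off, set) residues[p + off] %in% set,
               motif$offsets, motif$allowed)),
    logical(1))
  anchors[hits]
}

#' Serialize a motif in bracket notation
#'
#' Singleton sets print bare; the anchor prints as `P`. Example:
#' `"[STP]-P-[STP]-[TP]-[SP]"`.
#'
#' @param motif A [positional_motif].
#' @return A string.
#' @export
format_motif <- function(motif) {
  parts <- mapply(function(off, set) {
    if (off == 0) "P"
    else if (length(set) == 1) set
    else paste0("[", paste(set, collapse = ""), "]")
  }, motif$offsets, motif$allowed)
  paste(parts, collapse = "-")
}

#' Parse a motif from bracket notation
#'
#' Accepts `P` or `Pro` for the anchor and either bracketed sets or single
#' residues at other offsets, e.g. `"[AVSTG]-Pro-[AVSTG]-[GAVPSTC]-[APSDE]"`.
#' The anchor is taken to be the (unique) position written as `P`/`Pro`
#' outside brackets; the window is inferred from its index.
#'
#' @param text Motif string.
#' @param anchor_index Optional 1-based index of the anchor element, for
#'   motifs where `P` appears bare at more than one position.
#' @return A [positional_motif].
#' @export
parse_motif <- function(text, anchor_index = NULL) {
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  bare <- !grepl("^\\[", parts)
  sets <- lapply(parts, function(p) {
    p <- sub("^\\[", "", sub("\\]$", "", p))
    if (p == "Pro") p <- "P"
    strsplit(p, "")[[1]]
  })
  if (is.null(anchor_index)) {
    cand <- which(bare & vapply(sets, function(s) identical(s, "P"), logical(1)))
    if (length(cand) != 1)
      stop("anchor position ambiguous; supply anchor_index")
    anchor_index <- cand
  }
  window <- c(1L - anchor_index, length(parts) - anchor_index)
  positional_motif(sets, window)
}

#' Derive a consensus motif from sequences and site lists
#'
#' End-to-end wrapper: extract windows around each sequence's sites, pool
#' them, and build the union consensus.
#'
#' @param sequences Named character vector of peptide sequences.
#' @param sites List (parallel to `sequences`) of integer site vectors.
#' @param window c(start_offset, end_offset); default -1..+3.
#' @return A [positional_motif] with attribute `"skipped"` naming boundary
#'   sites excluded from derivation.
#' @export
derive_motif <- function(sequences, sites, window = c(-1L, 3L)) {
  mats <- mapply(function(seq, st) extract_windows(seq, st, window),
                 sequences, sites, SIMPLIFY = FALSE)
  skipped <- unlist(lapply(mats, attr, "skipped"))
  pooled <- do.call(rbind, mats)
  out <- consensus_motif(pooled, window)
  attr(out, "skipped") <- skipped
  out
}
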