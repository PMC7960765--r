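# File I/O: FASTA (via Biostrings), the ScanSet centroid-CSV dialect, and
# MGF peak lists for MS/MS spectra.

#' Read protein/peptide sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences; names are the full
#'   description lines.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector; names become description lines.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a centroided MS1 run from CSV
#'
#' The ScanSet CSV dialect has a mandatory header and one row per centroid
#' peak: columns `rt_min`, `mz`, `intensity`.
#'
#' @param path CSV file.
#' @param mz_tolerance_ppm Instrument tolerance to attach to the scan set.
#' @return A `scan_set` object.
#' @export
read_scanset_csv <- function(path, mz_tolerance_ppm = 10) {
  df <- utils::read.csv(path)
  need <- c("rt_min", "mz", "intensity")
  if (!all(need %in% names(df)))
    stop("ScanSet CSV must have columns rt_min, mz, intensity")
  rts <- sort(unique(df$rt_min))
  scans <- lapply(rts, function(rt) {
    sub <- df[df$rt_min == rt, , drop = FALSE]
    list(rt = rt, peaks = data.frame(mz = sub$mz, intensity = sub$intensity))
  })
  scan_set(scans, mz_tolerance_ppm = mz_tolerance_ppm)
}

#' Write a scan set to the ScanSet CSV dialect
#'
#' @param scans A `scan_set`.
#' @param path Output CSV.
#' @export
write_scanset_csv <- function(scans, path) {
  rows <- lapply(scans$scans, function(s) {
    if (!nrow(s$peaks)) return(NULL)
    data.frame(rt_min = s$rt, mz = s$peaks$mz, intensity = s$peaks$intensity)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a scan set
#'
#' @param scans List of scans, each `list(rt =, peaks = data.frame(mz, intensity))`,
#'   with strictly increasing retention times (minutes).
#' @param mz_tolerance_ppm Instrument m/z tolerance used at generation.
#' @return A `scan_set` object.
#' @export
scan_set <- function(scans, mz_tolerance_ppm = 10) {
  rts <- vapply(scans, function(s) s$rt, numeric(1))
  if (length(rts) > 1 && any(diff(rts) <= 0))
    stop("scan retention times must be strictly increasing")
  for (s in scans)
    if (nrow(s$peaks) && any(s$peaks$intensity < 0))
      stop("peak intensities must be non-negative")
  structure(list(scans = scans, mz_tolerance_ppm = mz_tolerance_ppm),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  npk <- sum(vapply(x$scans, function(s) nrow(s$peaks), integer(1)))
  rng <- range(vapply(x$scans, function(s) s$rt, numeric(1)))
  cat(sprintf("<scan_set> %d scans, %d peaks, rt %.3f-%.3f min, %g ppm\n",
              length(x$scans), npk, rng[1], rng[2], x$mz_tolerance_ppm))
  invisible(x)
}

#' Write MS/MS spectra to a Mascot Generic Format (MGF) file
#'
#' @param spectra List of spectra; each is a list with `title`, `pepmass`
#'   (precursor m/z), `charge`, and `peaks` (data.frame with `mz`,
#'   `intensity`).
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$title),
      sprintf("PEPMASS=%.6f", sp$pepmass),
      sprintf("CHARGE=%d+", as.integer(sp$charge)),
      sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read MS/MS spectra from an MGF file
#'
#' @param path MGF file.
#' @return List of spectra as in [write_mgf].
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS")
  mapply(function(s, e) {
    block <- lines[(s + 1):(e - 1)]
    is_header <- grepl("=", block, fixed = TRUE)
    hdr <- block[is_header]
    get <- function(key) {
      hit <- hdr[startsWith(hdr, paste0(key, "="))]
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
    }
    pk <- block[!is_header & nzchar(trimws(block))]
    fields <- do.call(rbind, lapply(strsplit(trimws(pk), "[ \t]+"), as.numeric))
    list(
      title = get("TITLE"),
      pepmass = as.numeric(strsplit(get("PEPMASS"), " ")[[1]][1]),
      charge = as.integer(sub("\\+$", "", get("CHARGE"))),
      peaks = if (is.null(fields)) data.frame(mz = numeric(), intensity = numeric())
              else data.frame(mz = fields[, 1], intensity = fields[, 2])
    )
  }, starts, ends, SIMPLIFY = FALSE)
}
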