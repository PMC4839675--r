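# Degenerate IUPAC motif scanning and tandem-array detection.
#
# Scans both strands of a DNA sequence for windows matching a degenerate
# consensus (the degeneracy is carried by IUPAC codes in the consensus,
# e.g. [AGGYGBYSYAGGACT]), then chains regularly spaced same-strand hits
# into tandem arrays. Coordinates are 0-based half-open internally and
# 1-based inclusive in report tables.

#' Does a base satisfy an IUPAC pattern character?
#'
#' @param pattern_char Single IUPAC nucleotide code.
#' @param base Single concrete base (A, C, G or T).
#' @return `TRUE` iff `base` is in the expansion of `pattern_char`.
#' @examples
#' iupac_match("Y", "C") # TRUE
#' @export
iupac_match <- function(pattern_char, base) {
  pattern_char <- toupper(pattern_char)
  base <- toupper(base)
  if (!pattern_char %in% names(.IUPAC)) {
    stop("invalid IUPAC code: ", pattern_char, call. = FALSE)
  }
  if (!base %in% c("A", "C", "G", "T")) {
    stop("invalid base: ", base, call. = FALSE)
  }
  base %in% .IUPAC[[pattern_char]]
}

# Mismatch counts of `pattern` (character vector of IUPAC codes) at every
# window start of `chars` (character vector over A/C/G/T/N). N in the
# subject never matches.
.window_mismatches <- function(chars, pattern) {
  n <- length(chars)
  L <- length(pattern)
  n_win <- n - L + 1L
  if (n_win < 1L) return(integer(0))
  mm <- integer(n_win)
  for (i in seq_len(L)) {
    ok <- chars[i:(i + n_win - 1L)] %in% .IUPAC[[pattern[i]]]
    mm <- mm + !ok
  }
  mm
}

#' Scan a sequence for a degenerate motif on both strands
#'
#' Reports every window, on the forward sequence and its reverse
#' complement, whose mismatch count against the consensus is at most
#' `max_mismatches`. `N` positions in the sequence never match. Minus
#' strand hits are reported in forward coordinates.
#'
#' @param seq DNA sequence (string over A/C/G/T/N; case-insensitive).
#' @param motif IUPAC consensus string, e.g. `"AGGYGBYSYAGGACT"`.
#' @param max_mismatches Maximum mismatches per window (default 0; the
#'   degeneracy lives in the consensus).
#' @return data.frame sorted by `start` with columns `start` (0-based),
#'   `end` (half-open), `strand` (`"+"`/`"-"`), `mismatches`. Empty when
#'   the sequence is shorter than the motif.
#' @export
scan_sequence <- function(seq, motif, max_mismatches = 0) {
  motif <- toupper(motif)
  pattern <- strsplit(motif, "")[[1]]
  if (!all(pattern %in% names(.IUPAC))) {
    stop("motif contains invalid IUPAC characters", call. = FALSE)
  }
  L <- length(pattern)
  if (max_mismatches >= L) {
    stop("max_mismatches must be smaller than the motif length", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence must be over A/C/G/T/N", call. = FALSE)
  }
  empty <- data.frame(
    start = integer(0), end = integer(0),
    strand = character(0), mismatches = integer(0)
  )
  if (length(chars) < L) return(empty)
  # minus strand: match the reverse complement of the motif against the
  # forward sequence, so coordinates stay in the forward frame
  rc_pattern <- strsplit(.revcomp(motif), "")[[1]]
  hits <- list(empty)
  for (strand in c("+", "-")) {
    p <- if (strand == "+") pattern else rc_pattern
    mm <- .window_mismatches(chars, p)
    keep <- which(mm <= max_mismatches)
    if (length(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = keep - 1L, end = keep - 1L + L,
        strand = strand, mismatches = mm[keep]
      )
    }
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Chain motif hits into tandem arrays
#'
#' Same-strand hits whose start-to-start distance is at most the motif
#' length plus `max_gap` are chained; chains of two or more units become
#' arrays. The default gap tolerance accommodates unit spacings somewhat
#' larger than the motif itself, as seen for regularly interspersed
#' repeat units at a differentially methylated region.
#'
#' @param hits data.frame from [scan_sequence()], sorted by `start`.
#' @param motif_length Length of the motif in bp.
#' @param max_gap Maximum gap between consecutive unit starts beyond the
#'   motif length (default 60 bp).
#' @return data.frame with one row per array: `strand`, `n_units`,
#'   `first_start` (0-based), `span_bp` (last hit end minus first hit
#'   start) and `starts` (comma-separated 0-based unit starts).
#' @export
find_tandem_arrays <- function(hits, motif_length, max_gap = 60) {
  if (nrow(hits) == 0L) {
    return(data.frame(
      strand = character(0), n_units = integer(0),
      first_start = integer(0), span_bp = integer(0),
      starts = character(0)
    ))
  }
  if (is.unsorted(hits$start)) {
    stop("hits must be sorted by start", call. = FALSE)
  }
  out <- list()
  for (strand in unique(hits$strand)) {
    h <- hits[hits$strand == strand, , drop = FALSE]
    gap_break <- c(TRUE, diff(h$start) > motif_length + max_gap)
    chain <- cumsum(gap_break)
    for (cid in unique(chain)) {
      hc <- h[chain == cid, , drop = FALSE]
      if (nrow(hc) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        strand = strand,
        n_units = nrow(hc),
        first_start = hc$start[1],
        span_bp = hc$end[nrow(hc)] - hc$start[1],
        starts = paste(hc$start, collapse = ",")
      )
    }
  }
  if (!length(out)) {
    return(data.frame(
      strand = character(0), n_units = integer(0),
      first_start = integer(0), span_bp = integer(0),
      starts = character(0)
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$first_start), , drop = FALSE]
}

#' Scan FASTA sequences for tandem arrays of a motif
#'
#' Driver over [scan_sequence()] and [find_tandem_arrays()] for each
#' sequence in a FASTA file or named character vector.
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @param motif IUPAC consensus string.
#' @param max_mismatches,max_gap See [scan_sequence()] and
#'   [find_tandem_arrays()].
#' @return List of two data.frames: `hits` (seq_id, start, end — 1-based
#'   inclusive — strand, mismatches) and `arrays` (seq_id, strand,
#'   n_units, first_start 1-based, span_bp, starts).
#' @export
scan_fasta_arrays <- function(fasta, motif, max_mismatches = 0, max_gap = 60) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    stats::setNames(as.character(x), names(x))
  } else {
    fasta
  }
  hit_rows <- list()
  arr_rows <- list()
  for (id in names(seqs)) {
    h <- scan_sequence(seqs[[id]], motif, max_mismatches = max_mismatches)
    a <- find_tandem_arrays(h, motif_length = nchar(motif), max_gap = max_gap)
    if (nrow(h)) {
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        seq_id = id, start = h$start + 1L, end = h$end,
        strand = h$strand, mismatches = h$mismatches
      )
    }
    if (nrow(a)) {
      arr_rows[[length(arr_rows) + 1L]] <- data.frame(
        seq_id = id, strand = a$strand, n_units = a$n_units,
        first_start = a$first_start + 1L, span_bp = a$span_bp,
        starts = a$starts
      )
    }
  }
  list(
    hits = if (length(hit_rows)) do.call(rbind, hit_rows) else NULL,
    arrays = if (length(arr_rows)) do.call(rbind, arr_rows) else NULL
  )
}
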