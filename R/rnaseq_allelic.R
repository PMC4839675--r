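# Allele-specific expression screen from raw read sets.
#
# Instead of aligning, each heterozygous SNP is interrogated with a
# 29-character substring of its flanking sequence carrying a single IUPAC
# ambiguity code at the SNP position. Expanding the code gives one
# concrete 29-mer per allele; reads containing either 29-mer (on either
# strand) are counted per allele, after a per-read Phred quality gate.
# The allele fraction then classifies the SNP as monoallelic, biallelic
# or biallelic-imbalanced, with a chi-square test against 50/50.

#' Construct and validate a SNP substring query
#'
#' @param snp_id SNP identifier.
#' @param substring 29-character string over A/C/G/T with exactly one
#'   biallelic IUPAC ambiguity code (R, Y, S, W, K or M) at the SNP
#'   position.
#' @return List of class `snp_query` with fields `snp_id`, `substring`,
#'   `position` (1-based ambiguity position), `allele_a`, `allele_b`
#'   (alphabetical order).
#' @examples
#' snp_query("rs2244352", paste0(strrep("A", 14), "Y", strrep("G", 14)))
#' @export
snp_query <- function(snp_id, substring) {
  substring <- toupper(substring)
  chars <- strsplit(substring, "")[[1]]
  if (length(chars) != 29L) {
    stop("query substring must be exactly 29 characters", call. = FALSE)
  }
  if (!all(chars %in% names(.IUPAC))) {
    stop("query contains non-IUPAC characters", call. = FALSE)
  }
  amb <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(amb) != 1L) {
    stop("query must contain exactly one ambiguity character, found ",
      length(amb),
      call. = FALSE
    )
  }
  bases <- .IUPAC[[chars[amb]]]
  if (length(bases) != 2L) {
    stop(sprintf(
      "ambiguity code '%s' encodes %d bases; need a biallelic code",
      chars[amb], length(bases)
    ), call. = FALSE)
  }
  structure(
    list(
      snp_id = snp_id, substring = substring, position = amb,
      allele_a = bases[1], allele_b = bases[2]
    ),
    class = "snp_query"
  )
}

#' Expand a SNP query into its two allelic 29-mers
#'
#' @param q A [snp_query()].
#' @return Named character vector `c(a = ..., b = ...)`, the two 29-mers
#'   differing only at the SNP position; allele `a` is the alphabetically
#'   first base of the ambiguity code.
#' @export
expand_query <- function(q) {
  stopifnot(inherits(q, "snp_query"))
  chars <- strsplit(q$substring, "")[[1]]
  sub_a <- chars
  sub_a[q$position] <- q$allele_a
  sub_b <- chars
  sub_b[q$position] <- q$allele_b
  c(a = paste(sub_a, collapse = ""), b = paste(sub_b, collapse = ""))
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file path.
#' @return List of class `read_set` with `id`, `seq` (character vector)
#'   and `qual` (list of integer Phred score vectors).
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(
    list(
      id = names(x),
      seq = unname(as.character(x)),
      qual = unname(as.list(methods::as(Biostrings::quality(x), "IntegerList")))
    ),
    class = "read_set"
  )
}

#' Write a read set to FASTQ
#'
#' @param reads A `read_set` (see [read_fastq()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  qual <- Biostrings::PhredQuality(vapply(
    reads$qual,
    function(q) rawToChar(as.raw(q + 33L)),
    character(1)
  ))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

.subset_reads <- function(reads, keep) {
  structure(
    list(
      id = reads$id[keep], seq = reads$seq[keep],
      qual = reads$qual[keep]
    ),
    class = "read_set"
  )
}

#' Filter reads by per-base quality
#'
#' A read passes when at least `min_fraction` of its bases have Phred
#' quality at or above `cutoff` (both boundaries inclusive) — the
#' standard per-read quality gate for raw read sets.
#'
#' @param reads A `read_set` with qualities.
#' @param cutoff Phred score cut-off (default 25).
#' @param min_fraction Minimum fraction of bases at or above the cut-off
#'   (default 0.9).
#' @return The passing subset, as a `read_set`.
#' @export
filter_reads <- function(reads, cutoff = 25, min_fraction = 0.9) {
  stopifnot(inherits(reads, "read_set"))
  if (is.null(reads$qual) || any(vapply(reads$qual, is.null, logical(1)))) {
    stop("reads are missing base qualities", call. = FALSE)
  }
  frac <- vapply(
    reads$qual,
    function(q) mean(q >= cutoff),
    numeric(1)
  )
  .subset_reads(reads, frac >= min_fraction)
}

#' Count allele-supporting reads for a SNP query
#'
#' A read supports allele `a` when it contains the allele-a 29-mer as an
#' exact substring of its forward sequence or reverse complement (and
#' symmetrically for allele `b`). Reads matching both expansions are
#' counted as ambiguous and excluded from depth.
#'
#' @param reads A (quality-filtered) `read_set`.
#' @param q A [snp_query()].
#' @return List with `snp_id`, `n_a`, `n_b`, `n_ambiguous`, `depth`
#'   (`n_a + n_b`).
#' @export
count_alleles <- function(reads, q) {
  stopifnot(inherits(reads, "read_set"), inherits(q, "snp_query"))
  subs <- expand_query(q)
  if (length(reads$seq) == 0L) {
    return(list(
      snp_id = q$snp_id, n_a = 0L, n_b = 0L,
      n_ambiguous = 0L, depth = 0L
    ))
  }
  fwd <- toupper(reads$seq)
  rev <- .revcomp(fwd)
  hit_a <- grepl(subs[["a"]], fwd, fixed = TRUE) |
    grepl(subs[["a"]], rev, fixed = TRUE)
  hit_b <- grepl(subs[["b"]], fwd, fixed = TRUE) |
    grepl(subs[["b"]], rev, fixed = TRUE)
  both <- hit_a & hit_b
  list(
    snp_id = q$snp_id,
    n_a = sum(hit_a & !both),
    n_b = sum(hit_b & !both),
    n_ambiguous = sum(both),
    depth = sum(hit_a & !both) + sum(hit_b & !both)
  )
}

#' Chi-square test of allelic counts against 50/50
#'
#' One-degree-of-freedom goodness of fit of the two allele counts against
#' equal expectation, without continuity correction; the statistic reduces
#' to `(n_a - n_b)^2 / depth`.
#'
#' @param n_a,n_b Non-negative allele read counts with `n_a + n_b > 0`.
#' @return List with `statistic` and `p_value` (upper tail, 1 df).
#' @examples
#' chisq_5050(60, 20) # statistic 20
#' @export
chisq_5050 <- function(n_a, n_b) {
  .check_finite_positive(n_a, "n_a", allow_zero = TRUE)
  .check_finite_positive(n_b, "n_b", allow_zero = TRUE)
  depth <- n_a + n_b
  if (any(depth == 0)) stop("depth must be positive", call. = FALSE)
  stat <- (n_a - n_b)^2 / depth
  list(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

#' Classify allelic expression from allele counts
#'
#' Below `min_depth` informative reads the SNP is not classified. Above
#' it, the allele-a fraction maps to: monoallelic below 0.15 or above
#' 0.85 (exclusive), biallelic within `[0.35, 0.65]` (inclusive),
#' biallelic imbalance in between (0.15 and 0.85 themselves fall in the
#' imbalance band). A chi-square test against 50/50 accompanies every
#' classified SNP.
#'
#' @param counts Result of [count_alleles()], or a list with `n_a`, `n_b`.
#' @param min_depth Minimum informative depth (default 80).
#' @param mono Monoallelic boundary (default 0.15; mirrored at
#'   `1 - mono`).
#' @param biallelic Biallelic band half-boundary (default 0.35; the band
#'   is `[biallelic, 1 - biallelic]`).
#' @return List with `fraction`, `category` (one of `"monoallelic"`,
#'   `"biallelic"`, `"biallelic_imbalance"`, `"insufficient_depth"`),
#'   `chi2`, `p_value` (NA when depth insufficient).
#' @examples
#' classify_expression(list(n_a = 60, n_b = 60))
#' @export
classify_expression <- function(counts, min_depth = 80, mono = 0.15,
                                biallelic = 0.35) {
  n_a <- counts$n_a
  n_b <- counts$n_b
  depth <- n_a + n_b
  if (depth < min_depth) {
    return(list(
      fraction = if (depth > 0) n_a / depth else NA_real_,
      category = "insufficient_depth",
      chi2 = NA_real_, p_value = NA_real_
    ))
  }
  f <- n_a / depth
  category <- if (f < mono || f > 1 - mono) {
    "monoallelic"
  } else if (f >= biallelic && f <= 1 - biallelic) {
    "biallelic"
  } else {
    "biallelic_imbalance"
  }
  test <- chisq_5050(n_a, n_b)
  list(
    fraction = f, category = category,
    chi2 = test$statistic, p_value = test$p_value
  )
}

#' Run the allelic expression screen over a set of SNP queries
#'
#' Quality-filters the reads once, then counts and classifies each query.
#'
#' @param reads A `read_set` (raw; filtered internally).
#' @param queries List of [snp_query()] objects, or a data.frame with
#'   columns `snp_id`, `substring`.
#' @param cutoff,min_fraction Passed to [filter_reads()].
#' @param ... Passed to [classify_expression()].
#' @return data.frame with one row per SNP: `snp_id`, `n_a`, `n_b`,
#'   `n_ambiguous`, `depth`, `fraction`, `category`, `chi2`, `p_value`.
#' @export
screen_expression <- function(reads, queries, cutoff = 25,
                              min_fraction = 0.9, ...) {
  if (is.data.frame(queries)) {
    queries <- Map(snp_query, queries$snp_id, queries$substring)
  }
  passing <- filter_reads(reads, cutoff = cutoff, min_fraction = min_fraction)
  rows <- lapply(queries, function(q) {
    ct <- count_alleles(passing, q)
    cl <- classify_expression(ct, ...)
    data.frame(
      snp_id = ct$snp_id, n_a = ct$n_a, n_b = ct$n_b,
      n_ambiguous = ct$n_ambiguous, depth = ct$depth,
      fraction = cl$fraction, category = cl$category,
      chi2 = cl$chi2, p_value = cl$p_value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
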