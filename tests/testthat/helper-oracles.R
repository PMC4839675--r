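# Independent oracles and small constructors used across the suite.

# Brute-force gamete-pair enumeration for trisomic locus origin: try every
# ordered pair of gametes from one parent plus a single gamete from the
# other, and see which side(s) can produce the child's allele multiset.
oracle_trisomy_origin <- function(mother, father, child_multiset) {
  child_key <- paste(sort(child_multiset), collapse = ",")
  side_ok <- function(dbl, single) {
    for (g1 in dbl) {
      for (g2 in dbl) {
        for (s in single) {
          if (paste(sort(c(g1, g2, s)), collapse = ",") == child_key) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }
  mat <- side_ok(mother, father)
  pat <- side_ok(father, mother)
  if (mat && pat) {
    "uninformative"
  } else if (mat) {
    "maternal"
  } else if (pat) {
    "paternal"
  } else {
    "inconsistent"
  }
}

# Naive position-by-position degenerate matcher (single strand, forward).
oracle_scan_forward <- function(seq, motif, max_mm = 0) {
  chars <- strsplit(toupper(seq), "")[[1]]
  pat <- strsplit(toupper(motif), "")[[1]]
  L <- length(pat)
  starts <- integer(0)
  mms <- integer(0)
  if (length(chars) < L) {
    return(data.frame(start = starts, mismatches = mms))
  }
  for (s in 0:(length(chars) - L)) {
    mm <- 0L
    for (i in seq_len(L)) {
      if (!methorigin::iupac_match(pat[i], chars[s + i])) mm <- mm + 1L
    }
    if (mm <= max_mm) {
      starts <- c(starts, s)
      mms <- c(mms, mm)
    }
  }
  data.frame(start = starts, mismatches = mms)
}

# Build a read_set directly from sequences and per-base qualities.
make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) {
    quals <- lapply(nchar(seqs), function(n) rep(40L, n))
  }
  structure(
    list(
      id = sprintf("read%03d", seq_along(seqs)),
      seq = unname(seqs),
      qual = quals
    ),
    class = "read_set"
  )
}

# A valid 29-mer query with a Y (C/T) ambiguity at position 15.
example_query <- function(snp_id = "rs_test") {
  methorigin::snp_query(
    snp_id,
    paste0("ACGTACGTACGTAC", "Y", "GTACGTACGTACGT")
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
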