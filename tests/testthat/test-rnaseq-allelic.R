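test_that("SNP queries validate the 29-character single-ambiguity contract", {
  q <- example_query()
  expect_equal(q$position, 15)
  expect_equal(q$allele_a, "C")
  expect_equal(q$allele_b, "T")
  ex <- expand_query(q)
  expect_equal(nchar(ex), c(a = 29L, b = 29L))
  expect_equal(substr(ex[["a"]], 15, 15), "C")
  expect_equal(substr(ex[["b"]], 15, 15), "T")
  # the two expansions differ only at the SNP position
  diff_pos <- which(strsplit(ex[["a"]], "")[[1]] != strsplit(ex[["b"]], "")[[1]])
  expect_equal(diff_pos, 15)
  expect_error(snp_query("x", strrep("A", 29)), "exactly one ambiguity")
  expect_error(
    snp_query("x", paste0(strrep("A", 14), "N", strrep("G", 14))),
    "biallelic"
  )
  expect_error(
    snp_query("x", paste0(strrep("A", 13), "YY", strrep("G", 14))),
    "exactly one ambiguity"
  )
  expect_error(snp_query("x", strrep("A", 28)), "29 characters")
})

test_that("per-read quality gate passes reads with >= 90% bases at Q25", {
  seqs <- rep(strrep("A", 100), 3)
  quals <- list(
    rep(30L, 100), # all high
    c(rep(30L, 89), rep(10L, 11)), # 89% -> fail
    c(rep(25L, 90), rep(10L, 10)) # exactly 90% at the cut-off -> pass
  )
  reads <- make_reads(seqs, quals)
  kept <- filter_reads(reads)
  expect_equal(kept$id, reads$id[c(1, 3)])
  bad <- reads
  bad$qual <- NULL
  expect_error(filter_reads(bad), "missing base qualities")
})

test_that("allele counting matches exact substrings on both strands", {
  q <- example_query()
  ex <- expand_query(q)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(ex[["a"]]))
  )
  set.seed(8)
  reads <- make_reads(c(
    paste0("GG", ex[["a"]], "TT"), # forward a
    paste0("AA", ex[["b"]]), # forward b
    paste0("T", rc, "ACGT"), # a on the reverse strand
    random_dna(40) # no match
  ))
  ct <- count_alleles(reads, q)
  expect_equal(ct$n_a, 2L)
  expect_equal(ct$n_b, 1L)
  expect_equal(ct$depth, 3L)
  expect_equal(ct$n_ambiguous, 0L)
  # a read carrying both expansions is ambiguous and excluded from depth
  both <- make_reads(paste0(ex[["a"]], "GG", ex[["b"]]))
  cb <- count_alleles(both, q)
  expect_equal(cb$n_ambiguous, 1L)
  expect_equal(cb$depth, 0L)
  # empty read set
  empty <- make_reads(character(0), list())
  expect_equal(count_alleles(empty, q)$depth, 0L)
})

test_that("reverse-complementing every read leaves allele counts unchanged", {
  q <- example_query()
  cfg <- sim_config(seed = 31, read_depth = 60)
  reads <- sim_reads(q, 0.4, cfg)
  flipped <- reads
  flipped$seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(reads$seq))
  )
  a <- count_alleles(reads, q)
  b <- count_alleles(flipped, q)
  expect_equal(a[c("n_a", "n_b", "n_ambiguous", "depth")],
    b[c("n_a", "n_b", "n_ambiguous", "depth")])
})

test_that("chi-square against 50/50 reduces to (n_a-n_b)^2/depth and matches chisq.test", {
  expect_equal(chisq_5050(40, 40)$statistic, 0)
  expect_equal(chisq_5050(40, 40)$p_value, 1)
  expect_equal(chisq_5050(60, 20)$statistic, 20)
  expect_equal(chisq_5050(41, 39)$statistic, 0.05)
  for (n_a in 0:60) {
    for (n_b in 0:(60 - n_a)) {
      if (n_a + n_b == 0) next
      got <- chisq_5050(n_a, n_b)
      ref <- suppressWarnings(stats::chisq.test(c(n_a, n_b), p = c(0.5, 0.5)))
      expect_equal(got$statistic, unname(ref$statistic))
      expect_equal(got$p_value, unname(ref$p.value))
    }
  }
  expect_error(chisq_5050(0, 0), "depth must be positive")
})

test_that("expression categories are total and symmetric on the fraction grid", {
  depth <- 100L
  n_as <- 0:100
  cats <- vapply(n_as, function(n) {
    classify_expression(list(n_a = n, n_b = depth - n))$category
  }, character(1))
  expect_true(all(cats %in% c("monoallelic", "biallelic", "biallelic_imbalance")))
  # symmetry about 0.5
  expect_equal(cats, rev(cats))
  # boundary placements (index = n_a at depth 100)
  at <- function(f) cats[round(f * 100) + 1]
  expect_equal(at(0.14), "monoallelic")
  expect_equal(at(0.15), "biallelic_imbalance")
  expect_equal(at(0.34), "biallelic_imbalance")
  expect_equal(at(0.35), "biallelic")
  expect_equal(at(0.50), "biallelic")
  expect_equal(at(0.65), "biallelic")
  expect_equal(at(0.66), "biallelic_imbalance")
  expect_equal(at(0.85), "biallelic_imbalance")
  expect_equal(at(0.86), "monoallelic")
})

test_that("the depth gate withholds classification below 80 informative reads", {
  r <- classify_expression(list(n_a = 30, n_b = 40))
  expect_equal(r$category, "insufficient_depth")
  expect_true(is.na(r$p_value))
  r2 <- classify_expression(list(n_a = 40, n_b = 40))
  expect_equal(r2$category, "biallelic")
  expect_false(is.na(r2$p_value))
})

test_that("type-I error is calibrated and monoallelic truth is recovered", {
  set.seed(123)
  n_a <- rbinom(1e4, 100, 0.5)
  p <- chisq_5050(n_a, 100L - n_a)$p_value
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
  n_a <- rbinom(1e4, 100, 0.95)
  cat95 <- ifelse(n_a / 100 > 0.85, "monoallelic", "other")
  cats <- vapply(seq_along(n_a), function(i) {
    classify_expression(list(n_a = n_a[i], n_b = 100L - n_a[i]))$category
  }, character(1))
  expect_gte(mean(cats == "monoallelic"), 0.99)
})

test_that("the screen recovers simulated expression regimes end to end", {
  q <- example_query()
  cfg <- sim_config(seed = 61, read_depth = 120)
  tab <- rbind(
    data.frame(truth = "monoallelic", f = 1.0),
    data.frame(truth = "biallelic", f = 0.5),
    data.frame(truth = "biallelic_imbalance", f = 0.25)
  )
  for (i in seq_len(nrow(tab))) {
    cfg_i <- sim_config(seed = 61 + i, read_depth = 120)
    reads <- sim_reads(q, tab$f[i], cfg_i)
    out <- screen_expression(reads, list(q))
    expect_equal(out$category, tab$truth[i], info = tab$truth[i])
  }
  # fraction 1.0 with zero errors yields no b reads at all
  cfg0 <- sim_config(seed = 62, read_depth = 50, base_error_rate = 0)
  expect_equal(count_alleles(sim_reads(q, 1.0, cfg0), q)$n_b, 0L)
})
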