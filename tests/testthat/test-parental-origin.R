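test_that("peak dosage resolution applies the ratio windows", {
  d <- dosage_from_peaks(c("a", "c"), c(1000, 500), ploidy = 3)
  expect_equal(d$pattern, "biallelic_21")
  expect_equal(d$dosage, c(a = 2L, c = 1L))
  t <- dosage_from_peaks(c("a", "b", "c"), c(300, 310, 295), ploidy = 3)
  expect_equal(t$pattern, "triallelic_111")
  expect_equal(t$dosage, c(a = 1L, b = 1L, c = 1L))
  # 1:1 biallelic peaks are incompatible with a 2:1 trisomic genotype
  o <- dosage_from_peaks(c("a", "c"), c(1000, 990), ploidy = 3)
  expect_equal(o$pattern, "other")
  expect_null(o$dosage)
  # window edges: 1.5 and 3.0 are callable, beyond is not
  expect_equal(
    dosage_from_peaks(c("a", "c"), c(1500, 1000), ploidy = 3)$pattern,
    "biallelic_21"
  )
  expect_equal(
    dosage_from_peaks(c("a", "c"), c(3100, 1000), ploidy = 3)$pattern,
    "other"
  )
  # disomic heterozygote
  expect_equal(
    dosage_from_peaks(c("a", "b"), c(500, 520), ploidy = 2)$dosage,
    c(a = 1L, b = 1L)
  )
  expect_error(dosage_from_peaks(c("a", "b"), c(0, 10)), ">")
  expect_error(dosage_from_peaks(letters[1:4], rep(1, 4)), "1-3 alleles")
})

test_that("locus segregation reproduces canonical trio configurations", {
  # triallelic child: both duplicated alleles maternal
  expect_equal(
    call_locus_segregation(c("a", "b"), c("c", "d"),
      c(a = 1L, b = 1L, c = 1L), 3)$origin,
    "maternal"
  )
  # doubled allele only transmissible by the father
  expect_equal(
    call_locus_segregation(c("a", "b"), c("c", "d"),
      c(c = 2L, a = 1L), 3)$origin,
    "paternal"
  )
  # both parental nondisjunction routes consistent
  expect_equal(
    call_locus_segregation(c("a", "a"), c("a", "b"),
      c(a = 2L, b = 1L), 3)$origin,
    "uninformative"
  )
  # child allele absent from both parents
  expect_equal(
    call_locus_segregation(c("a", "a"), c("b", "b"),
      c(c = 2L, a = 1L), 3)$origin,
    "inconsistent"
  )
  # disomic child: Mendelian check only, never informative for origin
  expect_equal(
    call_locus_segregation(c("a", "b"), c("c", "d"),
      c(a = 1L, c = 1L), 2)$origin,
    "uninformative"
  )
  expect_equal(
    call_locus_segregation(c("a", "a"), c("a", "a"),
      c(b = 1L, c = 1L), 2)$origin,
    "inconsistent"
  )
  # an uncallable dosage pattern is uninformative
  expect_equal(
    call_locus_segregation(c("a", "b"), c("c", "d"),
      list(pattern = "other", dosage = NULL), 3)$origin,
    "uninformative"
  )
})

test_that("locus segregation agrees with gamete-pair enumeration on all 4-allele configurations", {
  alleles <- c("a", "b", "c", "d")
  genos <- combn(rep(alleles, 2), 2, simplify = FALSE)
  genos <- unique(lapply(genos, sort))
  # all child multisets of size 3 over 4 alleles
  kids <- unique(lapply(
    combn(rep(alleles, 3), 3, simplify = FALSE), sort
  ))
  n_checked <- 0L
  for (m in genos) {
    for (f in genos) {
      for (k in kids) {
        dosage <- table(k)
        dosage <- stats::setNames(as.integer(dosage), names(dosage))
        got <- call_locus_segregation(m, f, dosage, 3)$origin
        expect_equal(got, oracle_trisomy_origin(m, f, k),
          info = sprintf(
            "M={%s} F={%s} child={%s}",
            paste(m, collapse = ","), paste(f, collapse = ","),
            paste(k, collapse = ",")
          )
        )
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_equal(n_checked, length(genos)^2 * length(kids))
})

test_that("family verdicts require three unanimous informative loci", {
  r <- aggregate_origin(c("maternal", "maternal", "maternal", "uninformative"))
  expect_equal(r$verdict, "MT21")
  expect_equal(r$n_informative, 3)
  expect_equal(aggregate_origin(c("maternal", "maternal"))$verdict,
    "indeterminate")
  expect_equal(
    aggregate_origin(c("maternal", "paternal", "maternal"))$verdict,
    "inconsistent"
  )
  expect_equal(
    aggregate_origin(rep("paternal", 4))$verdict, "PT21"
  )
  expect_equal(
    aggregate_origin(c(rep("maternal", 3), "inconsistent"))$verdict,
    "inconsistent"
  )
  expect_error(aggregate_origin(character(0)), "no locus calls")
})

test_that("simulated trios are never called for the wrong parent and verdicts match truth", {
  cfg <- sim_config(
    seed = 424, n_families = 500, n_str_loci = 5,
    str_allele_count = 8
  )
  sim <- sim_trios(cfg)
  res <- call_trio_origins(
    sim$genotypes,
    ploidy = stats::setNames(sim$truth$ploidy, sim$truth$family_id)
  )
  merged <- merge(res$families, sim$truth, by = "family_id")
  called <- merged[merged$verdict %in% c("MT21", "PT21"), ]
  expect_gt(nrow(called), 100)
  expect_equal(mean(called$verdict == called$origin), 1)
  # zero wrong-parent verdicts anywhere
  expect_false(any(
    (merged$verdict == "MT21" & merged$origin == "PT21") |
      (merged$verdict == "PT21" & merged$origin == "MT21")
  ))
})

test_that("relabeling mother and father flips every verdict", {
  cfg <- sim_config(seed = 77, n_families = 60)
  sim <- sim_trios(cfg)
  ploidy <- stats::setNames(sim$truth$ploidy, sim$truth$family_id)
  fwd <- call_trio_origins(sim$genotypes, ploidy = ploidy)$families
  swapped <- sim$genotypes
  swapped$person <- c(
    mother = "father", father = "mother", child = "child"
  )[swapped$person]
  rev <- call_trio_origins(swapped, ploidy = ploidy)$families
  map <- c(
    MT21 = "PT21", PT21 = "MT21",
    indeterminate = "indeterminate", inconsistent = "inconsistent"
  )
  expect_equal(rev$verdict, unname(map[fwd$verdict]))
})

test_that("androgenetic verification follows the homozygosity and exclusion rules", {
  loci <- sprintf("D%02d", 1:15)
  donor <- stats::setNames(
    lapply(1:15, function(i) c("x", "y")), loci
  )
  # homozygous everywhere, donor alleles absent at 5 loci
  sample_gt <- stats::setNames(
    lapply(1:15, function(i) if (i <= 5) "z" else "x"), loci
  )
  r <- verify_uniparental(sample_gt, donor)
  expect_equal(r$verdict, "androgenetic_consistent")
  expect_equal(r$n_excluding, 5)
  expect_equal(r$n_homozygous, 15)
  # any heterozygous locus breaks homogeneity
  het <- sample_gt
  het[[1]] <- c("z", "x")
  expect_equal(verify_uniparental(het, donor)$verdict, "not_homogeneous")
  # identical to the donor everywhere: maternal contribution not excluded
  same <- stats::setNames(lapply(1:15, function(i) "x"), loci)
  donor_same <- stats::setNames(lapply(1:15, function(i) "x"), loci)
  expect_equal(
    verify_uniparental(same, donor_same)$verdict,
    "not_androgenetic"
  )
  expect_error(
    verify_uniparental(sample_gt[1:5], donor[1:5]),
    "at least 10 shared loci"
  )
})
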