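#!/usr/bin/env Rscript
# Simulate the study cohort: 70 trisomy-21 trio families plus 20 disomic
# control families, genotyped at 5 STR loci with 8 equifrequent alleles,
# with the trisomic origin mix weighted toward maternal nondisjunction as
# observed clinically. Writes the trio genotype table and the truth
# manifest that downstream steps consume.

library(methorigin)

dir.create("results", showWarnings = FALSE)

cfg <- sim_config(
  seed = 20210,
  n_families = 90,
  origin_mix = c(N21 = 20 / 90, MT21 = 56 / 90, PT21 = 14 / 90),
  n_str_loci = 5,
  str_allele_count = 8
)

sim <- sim_trios(cfg)

write.table(sim$genotypes, "results/trio_genotypes.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
write.table(sim$truth, "results/trio_truth.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

cat(sprintf(
  "Simulated %d families (%d disomic, %d MT21, %d PT21) at %d STR loci.\n",
  nrow(sim$truth),
  sum(sim$truth$origin == "N21"),
  sum(sim$truth$origin == "MT21"),
  sum(sim$truth$origin == "PT21"),
  cfg$n_str_loci
))
cat("Wrote results/trio_genotypes.tsv and results/trio_truth.tsv\n")
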