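#!/usr/bin/env Rscript
# Allelic expression screen: simulate read sets for SNPs expressed under
# monoallelic, biallelic and imbalanced regimes (plus one shallow run
# below the depth gate), then count allele-supporting reads by 29-mer
# substring queries on both strands, quality-gate, classify the allele
# fraction and test against 50/50.

library(methorigin)

flank_l <- "ACGTTGCAGGTCCA" # 14 bases either side of the SNP
flank_r <- "GTCAAGGTTCACGT"
queries <- list(
  snp_query("rs_mono", paste0(flank_l, "Y", flank_r)),
  snp_query("rs_biallelic", paste0(flank_l, "R", flank_r)),
  snp_query("rs_imbalance", paste0(flank_l, "K", flank_r)),
  snp_query("rs_shallow", paste0(flank_l, "M", flank_r))
)
regimes <- data.frame(
  snp_id = c("rs_mono", "rs_biallelic", "rs_imbalance", "rs_shallow"),
  true_fraction = c(0.97, 0.50, 0.25, 0.50),
  depth = c(150, 150, 150, 40)
)

rows <- list()
for (i in seq_along(queries)) {
  cfg <- sim_config(seed = 20240 + i, read_depth = regimes$depth[i])
  reads <- sim_reads(queries[[i]], regimes$true_fraction[i], cfg)
  rows[[i]] <- screen_expression(reads, queries[i])
}
screen <- do.call(rbind, rows)
screen$true_fraction <- regimes$true_fraction

write.table(screen, "results/allele_expression.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

cat("Allelic expression screen:\n")
print(screen[, c("snp_id", "depth", "fraction", "category", "chi2", "p_value")],
  row.names = FALSE, digits = 3
)

# chi-square calibration under balanced expression at the depth gate
set.seed(20249)
n_a <- rbinom(1e4, 100, 0.5)
typeI <- mean(chisq_5050(n_a, 100L - n_a)$p_value < 0.05)
cat(sprintf(
  "\nType-I error of the 50/50 chi-square at depth 100 (10^4 sims): %.4f\n",
  typeI
))
cat("Wrote results/allele_expression.tsv\n")
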