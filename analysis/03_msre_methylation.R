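#!/usr/bin/env Rscript
# MSRE-PCR methylation quantification at the candidate DMR. Simulates
# peak-area quartets for every cohort sample around its dosage-expected
# methylation (disomic 50%, maternal-origin trisomy 200/3%, paternal
# 100/3%), plus an androgenetic mole (0%: no maternal imprint) and an
# hESC-like hypermethylated reference (82%), then quantifies %Meth with
# the imbalance-corrected estimator, classifies methylation states, and
# classifies trisomic samples as MT21/PT21 from %Meth alone.

library(methorigin)

truth <- read.delim("results/trio_truth.tsv")
verdicts <- read.delim("results/origin_verdicts.tsv")

expected <- c(N21 = 50, MT21 = 200 / 3, PT21 = 100 / 3)
samples <- data.frame(
  sample_id = truth$family_id,
  group = truth$origin,
  true_meth = unname(expected[truth$origin])
)
samples <- rbind(
  samples,
  data.frame(sample_id = "ACHM", group = "ACHM", true_meth = 0),
  data.frame(sample_id = "hESC", group = "hESC", true_meth = 82)
)

cfg <- sim_config(seed = 20230, meth_noise_cv = 0.03)
quartets <- cbind(
  sample_id = samples$sample_id, target = "DMR_CGI2",
  sim_msre(samples$true_meth, cfg, n = nrow(samples))
)

meth <- quantify_methylation(quartets)
meth$group <- samples$group
meth$epigenetic_verdict <- NA
tri <- meth$group %in% c("MT21", "PT21")
meth$epigenetic_verdict[tri] <- epigenetic_origin(meth$percent_meth[tri])

write.table(meth, "results/msre_methylation.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)

means <- aggregate(percent_meth ~ group, meth, mean)
cat("Group mean %Meth:\n")
print(means, row.names = FALSE)

epi <- meth[tri, ]
cat(sprintf(
  "\nEpigenetic MT21/PT21 classification: %d/%d called, %.1f%% of calls correct.\n",
  sum(epi$epigenetic_verdict != "indeterminate"), nrow(epi),
  100 * mean(
    epi$epigenetic_verdict[epi$epigenetic_verdict != "indeterminate"] ==
      epi$group[epi$epigenetic_verdict != "indeterminate"]
  )
))

# concordance with the STR-based verdicts where both methods called
both <- merge(
  epi[, c("sample_id", "epigenetic_verdict")],
  verdicts[, c("family_id", "verdict")],
  by.x = "sample_id", by.y = "family_id"
)
both <- both[both$verdict %in% c("MT21", "PT21") &
  both$epigenetic_verdict != "indeterminate", ]
cat(sprintf(
  "STR vs epigenetic concordance on %d doubly-called samples: %.1f%%\n",
  nrow(both), 100 * mean(both$verdict == both$epigenetic_verdict)
))
cat("Wrote results/msre_methylation.tsv\n")
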