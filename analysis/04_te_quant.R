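#!/usr/bin/env Rscript

## Step 4 - retrotransposon quantification.
##
## Once-per-read TE group RPM per library, KO/WT upregulation ranking at
## 9 d.p.p., the antisense perfect-match length profile against FLI IAP
## insertions, and per-subfamily divergence (boxplot) summaries.

library(pirnascape)

seed <- 1
dir.create("results", showWarnings = FALSE)

cfg <- sim_config_testes(seed = seed)
sim <- simulate_dataset(cfg)
design <- cfg$design

rpm <- te_group_rpm(sim$reads_by_sample, sim$te, sim$libs)
write.table(cbind(group = rownames(rpm), as.data.frame(rpm)),
            "results/te_group_rpm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ids_9 <- design$sample_id[design$timepoint == "9dpp"]
gmean <- function(g) rowMeans(rpm[, intersect(
  ids_9, design$sample_id[design$genotype == g]), drop = FALSE])
ranked <- rank_upregulated(gmean("WT"), gmean("KO"))
write.table(ranked, "results/te_upregulated_9dpp.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("KO/WT fold changes at 9 d.p.p. (planted 20 / 3.3 / 2):")
for (i in seq_len(nrow(ranked)))
  message(sprintf("  %-8s %6.2f-fold", ranked$group[i],
                  ranked$fold_change[i]))

fli <- sim$te[sim$te$is_fli, ]
anti <- do.call(rbind, lapply(
  design$sample_id[design$genotype == "WT"], function(s)
    cbind(sample_id = s,
          antisense_length_profile(sim$reads_by_sample[[s]], fli,
                                   sim$libs[sim$libs$sample_id == s, ]))))
write.table(anti, "results/fli_iap_antisense_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

div <- divergence_summary(sim$te)
write.table(div, "results/te_divergence_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf(
  "antisense FLI IAP profile peaks at %d nt; %d subfamilies summarized",
  anti$length[which.max(anti$rpm)], nrow(div)))
message("tables -> results/te_{group_rpm,upregulated_9dpp,divergence_summary}.tsv")
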