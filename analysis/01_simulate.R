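#!/usr/bin/env Rscript

## Step 1 - generate the synthetic study data.
##
## Builds the two shipped simulation configurations (testes knockout/wild-type
## time course; oocyte PIWI-IP design), simulates every library with planted
## ground truth, and writes the full datasets (chrom.sizes, gaps, RepeatMasker
## annotation, per-sample alignments, truth tables) under scratch/simdata/.
## Small per-library summaries go to results/.

library(pirnascape)

seed <- 1
dir.create("results", showWarnings = FALSE)

message("simulating testes dataset (WT/KO x 9/13/21 d.p.p. x 2 replicates)...")
testes <- simulate_dataset(sim_config_testes(seed = seed))
write_sim_dataset(testes, "scratch/simdata/testes")

message("simulating oocyte dataset (PIWIL1/PIWIL3 IP + WT/KO oocytes)...")
oocyte <- simulate_dataset(sim_config_oocyte(seed = seed))
write_sim_dataset(oocyte, "scratch/simdata/oocyte")

libs <- rbind(cbind(dataset = "testes", testes$truth$libraries),
              cbind(dataset = "oocyte", oocyte$truth$libraries))
write.table(libs, "results/library_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf(
  "done: %d testes libraries (%s reads total), %d oocyte libraries (%s reads total)",
  nrow(testes$truth$libraries),
  format(sum(testes$truth$libraries$n_reads), big.mark = ","),
  nrow(oocyte$truth$libraries),
  format(sum(oocyte$truth$libraries$n_reads), big.mark = ",")))
message("library summary -> results/library_summary.tsv")
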