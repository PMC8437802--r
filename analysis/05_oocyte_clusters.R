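#!/usr/bin/env Rscript

## Step 5 - oocyte piRNA cluster definition.
##
## Seeds candidate windows from the PIWIL1/PIWIL3 IP libraries, merges them
## into superclusters and applies the two inclusive 10-RPM retention filters
## (IP signal; combined 18-20 + 24-32-nt wild-type signal excluding the
## 21-23-nt miRNA/siRNA population).

library(pirnascape)

seed <- 1
dir.create("results", showWarnings = FALSE)

cfg <- sim_config_oocyte(seed = seed)
sim <- simulate_dataset(cfg)
res <- run_oocyte_pipeline(sim)

write.table(res$candidates, "results/oocyte_cluster_candidates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$clusters, "results/oocyte_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_clusters_bed(res$clusters, "results/oocyte_clusters.bed")

planted <- cfg$clusters[cfg$clusters$name != "oo_decoy", ]
key <- function(df) paste(df$chrom, df$start, df$end)
message(sprintf("%d candidate loci, %d retained after the 10-RPM filters",
                nrow(res$candidates), nrow(res$clusters)))
message(sprintf("planted oocyte clusters recovered exactly: %s",
                setequal(key(res$clusters), key(planted))))
message(sprintf(
  "decoy (IP-positive, %.1f RPM wild-type combined signal) rejected: %s",
  res$candidates$wt_combined_rpm[
    res$candidates$start == cfg$clusters$start[4]][1],
  !any(res$clusters$start == cfg$clusters$start[4])))
message("tables -> results/oocyte_cluster{s,_candidates}.tsv")
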