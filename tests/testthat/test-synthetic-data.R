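## The generator defines the study conditions; these tests check its
## contracts on a scaled-down library so they stay fast.

test_that("simulation is fully deterministic under (seed, config)", {
  cfg <- small_testes_config(seed = 5, depth = 5000)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$reads_by_sample, s2$reads_by_sample)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$te, s2$te)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_dataset(small_testes_config(seed = 6, depth = 5000))
  expect_false(identical(s1$reads_by_sample, s3$reads_by_sample))
})

test_that("gap placement honours the configured fraction and avoids clusters", {
  cfg <- small_testes_config(seed = 9, depth = 1000)
  set.seed(cfg$seed)
  sg <- simulate_genome(cfg)
  gaps <- sg$genome$gaps
  expect_equal(sum(gaps$end - gaps$start),
               cfg$gap_fraction * sum(cfg$chrom_lengths),
               tolerance = cfg$gap_unit / sum(cfg$chrom_lengths))
  gap_gr <- GenomicRanges::GRanges(gaps$chrom,
                                   IRanges::IRanges(gaps$start + 1, gaps$end))
  cl_gr <- GenomicRanges::GRanges(cfg$clusters$chrom,
                                  IRanges::IRanges(cfg$clusters$start + 1,
                                                   cfg$clusters$end))
  expect_equal(sum(IRanges::overlapsAny(gap_gr, cl_gr)), 0)

  cfg0 <- small_testes_config(seed = 9, depth = 1000)
  cfg0$gap_fraction <- 0
  set.seed(cfg0$seed)
  expect_equal(nrow(simulate_genome(cfg0)$genome$gaps), 0)
})

test_that("multimap_rate 0 yields unique mappers only", {
  cfg <- small_testes_config(seed = 4, depth = 5000)
  cfg$multimap_rate <- 0
  sim <- simulate_dataset(cfg)
  expect_true(all(vapply(sim$reads_by_sample,
                         function(r) all(r$n_hits == 1L), TRUE)))
})

test_that("multimappers carry consistent n_hits across their records", {
  cfg <- small_testes_config(seed = 4, depth = 20000)
  sim <- simulate_dataset(cfg)
  r <- sim$reads_by_sample[[1]]
  per_read <- tapply(r$n_hits, r$read_id, function(x) length(unique(x)))
  expect_true(all(per_read == 1))
  multi <- r[r$n_hits > 1, ]
  recs <- table(multi$read_id)
  expect_true(all(recs == multi$n_hits[match(names(recs), multi$read_id)]))
  prim <- tapply(r$is_primary, r$read_id, sum)
  expect_true(all(prim == 1))
})

test_that("knockout libraries with retention 0 have no cluster reads", {
  cfg <- small_testes_config(seed = 13, depth = 20000)
  sim <- simulate_dataset(cfg)
  pre <- cfg$clusters[cfg$clusters$stage == "pre_pachytene", ]
  for (s in c("ko_9_r1", "ko_13_r2"))
    expect_equal(nrow(reads_in_intervals(sim$reads_by_sample[[s]], pre)), 0)
  ## and the corresponding wild-type libraries are populated there
  expect_gt(nrow(reads_in_intervals(sim$reads_by_sample$wt_9_r1, pre)), 0)
})

test_that("planted cluster read counts follow the configured rates", {
  cfg <- small_testes_config(seed = 19, depth = 5e4)
  sim <- simulate_dataset(cfg)
  cl <- cfg$clusters[1, ]   # 3 kb at 40 RPM/kb
  expected <- cl$wt_rpm_per_kb * 3 * cfg$depth / 1e6
  got <- length(unique(
    reads_in_intervals(sim$reads_by_sample$wt_9_r1, cl)$read_id))
  expect_lt(abs(got - expected), 4 * sqrt(expected))
})

test_that("planted 1U/10A biases appear in the emitted sequences", {
  cfg <- small_testes_config(seed = 23, depth = 5e5)
  set.seed(cfg$seed)
  sg <- simulate_genome(cfg)
  r <- simulate_library(cfg, sg, "wt_21_r1")$reads
  seqs <- r$sequence[!is.na(r$sequence) & r$is_primary]
  n <- length(seqs)
  expect_gt(n, 200)
  u1 <- mean(substr(seqs, 1, 1) == "T")
  a10 <- mean(substr(seqs, 10, 10) == "A")
  expect_lt(abs(u1 - cfg$u1_prob), 4 * sqrt(0.8 * 0.2 / n))
  expect_lt(abs(a10 - cfg$a10_prob), 4 * sqrt(0.5 * 0.5 / n))
})

test_that("truth tables audit against the emitted libraries", {
  cfg <- small_testes_config(seed = 3, depth = 5000)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$clusters), nrow(cfg$clusters))
  for (s in names(sim$reads_by_sample)) {
    expect_equal(sim$truth$libraries$n_records[
      sim$truth$libraries$sample_id == s],
      nrow(sim$reads_by_sample[[s]]))
  }
  ## a corrupted library is caught by the audit
  bad <- sim$reads_by_sample
  bad[[1]] <- bad[[1]][-1, ]
  expect_error(pirnascape:::audit_truth(bad, sim$truth), "self-audit")
})

test_that("written datasets round-trip and pass the on-disk audit", {
  cfg <- small_testes_config(seed = 2, depth = 2000)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  gm <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  gm <- read_gaps_bed(file.path(dir, "gaps.bed"), gm)
  expect_equal(gm$chroms, sim$genome$chroms)
  expect_equal(gm$gaps, sim$genome$gaps, ignore_attr = TRUE)
  te <- read_repeatmasker_out(file.path(dir, "repeats.out"),
                              read_group_map(file.path(dir, "group_map.tsv")))
  te <- mark_fli(te, file.path(dir, "fli.bed"))
  expect_equal(te[, c("chrom", "start", "end", "strand", "subfamily",
                      "group", "milli_div", "is_fli")],
               sim$te[, c("chrom", "start", "end", "strand", "subfamily",
                          "group", "milli_div", "is_fli")],
               ignore_attr = TRUE)
  s <- names(sim$reads_by_sample)[1]
  back <- read_alignments(file.path(dir, "alignments", paste0(s, ".tsv")))
  expect_equal(back, sim$reads_by_sample[[s]], ignore_attr = TRUE)
})

test_that("simulated KO/WT window ratios converge to the retention fraction", {
  cfg <- sim_config_oocyte(seed = 15, depth = 5e4)
  sim <- simulate_dataset(cfg)
  cl <- cfg$clusters[1, ]   # retention 0.05, strong cluster
  wt_n <- length(unique(
    reads_in_intervals(sim$reads_by_sample$wt_oo_r1, cl)$read_id))
  ko_n <- length(unique(
    reads_in_intervals(sim$reads_by_sample$ko_oo_r1, cl)$read_id))
  expected_wt <- cl$wt_rpm_per_kb * 3 * cfg$depth / 1e6
  expected_ko <- expected_wt * cl$ko_retention
  expect_lt(abs(wt_n - expected_wt), 4 * sqrt(expected_wt))
  expect_lt(abs(ko_n - expected_ko), 4 * sqrt(expected_ko) + 2)
})

test_that("configuration validation rejects inconsistent inputs", {
  cfg <- small_testes_config()
  bad <- cfg
  expect_error(do.call(sim_config, {
    a <- unclass(cfg); a$u1_prob <- 1.4; a
  }), "\\[0, 1\\]")
  expect_error(do.call(sim_config, {
    a <- unclass(cfg); a$clusters$end[1] <- 2e6; a
  }), "outside chromosome")
  expect_error(do.call(sim_config, {
    a <- unclass(cfg); a$depth <- 0; a
  }), "depth")
  expect_error(do.call(sim_config, {
    a <- unclass(cfg); a$length_dist$pachytene <- c("28" = 0.5); a
  }), "sum to 1")
})
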