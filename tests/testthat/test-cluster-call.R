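test_that("log2 fold change follows its closed form and is antisymmetric", {
  expect_equal(log2_fold_change(1, 4, pseudocount = 0), -2)
  expect_equal(log2_fold_change(0, 10, 0.01), log2(0.01 / 10.01))
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(-1, 2), "non-negative")
  set.seed(3)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("pseudocount perturbs expressed windows within the analytic bound", {
  set.seed(8)
  for (i in 1:50) {
    ko <- runif(1, 0.1, 50); wt <- runif(1, 0.1, 50)
    p <- runif(1, 0.001, 0.1)
    x <- min(ko, wt)
    bound <- log2((x + p) / x)
    expect_lte(abs(log2_fold_change(ko, wt, p) - log2_fold_change(ko, wt, 0)),
               bound + 1e-12)
  }
})

test_that("stage classification applies strict inequalities at the threshold", {
  fc <- data.frame(lfc_9dpp = c(-3, 0, -3, -2.001, -3),
                   lfc_13dpp = c(-2.5, -1, -2, -2.5, -1.99),
                   lfc_21dpp = c(-1, -3, -1, -1, -3))
  expect_equal(classify_windows(fc),
               c("pre_pachytene",  # lower than -2 at 9 and 13
                 "pachytene",      # lower than -2 at 21, higher at 13
                 NA,               # lfc_13 exactly -2 satisfies neither rule
                 "pre_pachytene",
                 "pachytene"))
})

test_that("adjacent same-stage windows merge; labels and gaps split", {
  wdf <- function(starts, stages, chrom = "chr1")
    data.frame(chrom = chrom, start = starts, end = starts + 1000,
               stage = stages, stringsAsFactors = FALSE)
  one <- merge_adjacent(wdf(c(0, 1000), rep("pre_pachytene", 2)))
  expect_equal(one[, c("start", "end", "n_windows")],
               data.frame(start = 0, end = 2000, n_windows = 2L),
               ignore_attr = TRUE)
  two <- merge_adjacent(wdf(c(0, 1000), c("pre_pachytene", "pachytene")))
  expect_equal(nrow(two), 2)
  gapped <- merge_adjacent(wdf(c(0, 2000), rep("pre_pachytene", 2)))
  expect_equal(nrow(gapped), 2)
  expect_error(merge_adjacent(wdf(c(1000, 0), rep("pachytene", 2))),
               "sorted")
})

test_that("superclusters merge at gap <= 2000, are idempotent and order-invariant", {
  cl <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(3000, 8000),
                   stage = "pre_pachytene", n_windows = c(3L, 3L),
                   stringsAsFactors = FALSE)
  merged <- merge_superclusters(cl, 2000)
  expect_equal(merged$start, 0)
  expect_equal(merged$end, 8000)
  expect_equal(merged$n_windows, 6L)

  cl2 <- cl; cl2$start[2] <- 5001; cl2$end[2] <- 8001
  expect_equal(nrow(merge_superclusters(cl2, 2000)), 2)

  expect_equal(merge_superclusters(merged, 2000), merged)
  shuffled <- cl[c(2, 1), ]
  expect_equal(merge_superclusters(shuffled, 2000), merged)

  ## stages never mix even within the gap
  mixed <- cl; mixed$stage <- c("pre_pachytene", "pachytene")
  expect_equal(nrow(merge_superclusters(mixed, 2000)), 2)
})

test_that("final RPKM recomputation and density follow their definitions", {
  gm <- genome_model("chr1", 10000)
  cl <- data.frame(chrom = "chr1", start = 0, end = 2000,
                   stage = "pre_pachytene", n_windows = 2L,
                   stringsAsFactors = FALSE)
  reads <- setNames(lapply(design6()$sample_id, function(s)
    if (s %in% c("wt9", "wt13")) reads_in(20, 0, 2000, prefix = s)
    else empty_aln()), design6()$sample_id)
  out <- finalize_clusters(cl, reads, gm, libs_for(design6()$sample_id, 1e6),
                           design6())
  expect_equal(out$wt_rpm, 20)             # mean of WT 9 and 13 d.p.p.
  expect_equal(out$rpkm_WT_9dpp, 10)       # 20 RPM over 2 kb
  expect_equal(out$density, 10)            # RPM per kb
  expect_equal(out$rpkm_KO_9dpp, 0)

  ## fully gapped interval is dropped
  gm2 <- genome_model("chr1", 10000,
                      gaps = data.frame(chrom = "chr1", start = 0, end = 2000))
  expect_warning(
    out2 <- finalize_clusters(cl, reads, gm2,
                              libs_for(design6()$sample_id, 1e6), design6()),
    "gapped")
  expect_equal(nrow(out2), 0)

  ## declarative curation replaces manual curation
  cur <- data.frame(chrom = "chr1", start = 0, end = 2000,
                    action = "exclude", stringsAsFactors = FALSE)
  expect_message(
    out3 <- finalize_clusters(cl, reads, gm, libs_for(design6()$sample_id, 1e6),
                              design6(), curation = cur),
    "curation")
  expect_equal(nrow(out3), 0)
})

test_that("density filtering is strictly greater-than per stage", {
  cl <- data.frame(chrom = "chr1", start = 0, end = c(2000, 4000, 6000, 8000),
                   stage = c("pre_pachytene", "pre_pachytene",
                             "pachytene", "pachytene"),
                   n_windows = 2L, effective_length = 2000,
                   wt_rpm = c(20, 22, 300, 150), density = c(10, 11, 150, 75),
                   stringsAsFactors = FALSE)
  kept <- filter_density(cl)
  expect_equal(kept$density, c(11, 150))   # exactly 10 rejected, 75 < 100
  ## alternative reading: 100 RPM total per pachytene cluster
  kept2 <- filter_density(cl, pachytene_per_kb = FALSE)
  expect_equal(kept2$wt_rpm, c(22, 300, 150))
})

test_that("pipeline matches the brute-force enumeration on random instances", {
  set.seed(2024)
  for (i in 1:12) {
    inst <- random_instance()
    thr <- sample(c(10, 200, 1000), 2, TRUE)
    rb <- run_both(inst, thr[1], thr[2])
    expect_equal(rb$got[, c("chrom", "start", "end", "stage", "n_windows")],
                 rb$want[, c("chrom", "start", "end", "stage", "n_windows")],
                 ignore_attr = TRUE)
    expect_equal(rb$got$density, rb$want$density, tolerance = 1e-9)
    ## no same-stage output interval overlaps another
    for (st in unique(rb$got$stage)) {
      g <- rb$got[rb$got$stage == st, ]
      if (nrow(g) > 1) {
        g <- g[order(g$start), ]
        expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
      }
    }
  }
})

test_that("oocyte cluster filters honour the inclusive 10-RPM thresholds", {
  gm <- genome_model("chr1", 20000)
  w <- tile_genome(gm, 1000)
  mk_ip <- function(vals, sample) window_table(w, matrix(vals, ncol = 1),
                                               "RPM", samples = sample)
  ## four candidate windows > 2 kb apart (indices 1, 5, 9, 13)
  v1 <- numeric(20); v1[c(1, 5, 9, 13)] <- c(12, 10, 12, 12)
  v3 <- numeric(20); v3[c(1, 5, 9, 13)] <- 3
  p1 <- mk_ip(v1, "piwil1")
  p3 <- mk_ip(v3, "piwil3")
  libs <- libs_for(c("oo1", "oo2"), 1e6)
  ## WT oocyte reads: cluster 1 rich (19 + 28 nt), cluster 2 rich, cluster 3
  ## below 10 RPM combined, cluster 4 only 21-23-nt reads
  wt1 <- rbind(reads_in(8, 0, 1000, "a", read_length = 19),
               reads_in(7, 0, 1000, "b", read_length = 28),
               reads_in(12, 4000, 5000, "c", read_length = 26),
               reads_in(9, 8000, 9000, "d", read_length = 28),
               reads_in(40, 12000, 13000, "e", read_length = 22))
  reads <- list(oo1 = wt1, oo2 = wt1)
  res <- call_oocyte_clusters(p1, p3, reads, libs)
  expect_equal(res$candidates$retained, c(TRUE, TRUE, FALSE, FALSE))
  ## cluster 1: PIWIL1 12 >= 10, combined 15 RPM -> retained
  ## cluster 2: PIWIL1 exactly 10 ("a minimum of 10") -> retained
  expect_equal(res$clusters$start, c(0, 4000))
  ## cluster 3: combined 9 < 10 -> removed; cluster 4: only 21-23 nt -> 0
  expect_equal(res$candidates$wt_combined_rpm[4], 0)

  ## tiling mismatch is an error
  w2 <- tile_genome(genome_model("chr1", 9000), 1000)
  p3_bad <- window_table(w2, matrix(0, 9, 1), "RPM", samples = "piwil3")
  expect_error(call_oocyte_clusters(p1, p3_bad, reads, libs), "tiling")
})
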