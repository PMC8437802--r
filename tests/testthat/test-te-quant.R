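te_df <- function(chrom, start, end, strand = "+", subfamily = "IAPEz-int",
                  group = "IAP", class = "LTR", milli_div = 30,
                  is_fli = FALSE) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             subfamily = subfamily, group = group, class = class,
             milli_div = milli_div, is_fli = is_fli, stringsAsFactors = FALSE)
}

test_that("a read counts once per group no matter how many insertions it hits", {
  te <- rbind(te_df("chr1", 1000, 3000, subfamily = "MYSERV6-int",
                    group = "MYSERV6"),
              te_df("chr1", 5000, 7000, subfamily = "MYSERV6-int",
                    group = "MYSERV6"),
              te_df("chr1", 9000, 11000, subfamily = "MYSERV6-int",
                    group = "MYSERV6"),
              te_df("chr1", 20000, 26000),
              te_df("chr1", 30000, 36000, subfamily = "L1-Ham", group = "L1",
                    class = "LINE"))
  ## three alignments of one read in three MYSERV6 insertions -> MYSERV6 +1
  r1 <- rbind(aln("multi", 1500, n_hits = 3L),
              aln("multi", 5500, n_hits = 3L, is_primary = FALSE),
              aln("multi", 9500, n_hits = 3L, is_primary = FALSE))
  ## one read hitting an IAP and an L1 insertion -> both groups +1
  r2 <- rbind(aln("dual", 20500, n_hits = 2L),
              aln("dual", 30500, n_hits = 2L, is_primary = FALSE))
  ## read overlapping nothing
  r3 <- aln("lost", 50000)
  counts <- assign_reads_once(rbind(r1, r2, r3), te)
  expect_equal(counts, c(IAP = 1, L1 = 1, MYSERV6 = 1))

  ## unique_global: the dual read goes to the group with most alignments,
  ## ties broken lexicographically -> IAP
  ug <- assign_reads_once(rbind(r1, r2, r3), te, mode = "unique_global")
  expect_equal(ug, c(IAP = 1, L1 = 0, MYSERV6 = 1))
})

test_that("once-per-read counting matches a set-membership brute force", {
  set.seed(17)
  n_ins <- 30
  te <- te_df("chr1", start = seq(0, by = 5000, length.out = n_ins),
              end = seq(2000, by = 5000, length.out = n_ins),
              subfamily = sample(c("A-int", "B-int", "C-int"), n_ins, TRUE))
  te$group <- sub("-int", "", te$subfamily)
  n_reads <- 150
  reads <- do.call(rbind, lapply(seq_len(n_reads), function(i) {
    k <- sample(c(1L, 1L, 2L, 3L), 1)
    starts <- sample(0:150000, k)
    do.call(rbind, lapply(seq_len(k), function(j)
      aln(paste0("r", i), starts[j], n_hits = k, is_primary = j == 1)))
  }))
  got <- assign_reads_once(reads, te, group_by = "group")
  ## oracle: per read, the set of groups any alignment overlaps
  want <- setNames(numeric(3), c("A", "B", "C"))
  for (id in unique(reads$read_id)) {
    r <- reads[reads$read_id == id, ]
    hit <- character()
    for (j in seq_len(nrow(r)))
      for (k in seq_len(nrow(te)))
        if (r$start[j] < te$end[k] && te$start[k] < r$end[j])
          hit <- union(hit, te$group[k])
    for (g in hit) want[g] <- want[g] + 1
  }
  expect_equal(got, want)
  expect_true(all(got <= length(unique(reads$read_id))))
})

test_that("antisense profiles demand opposite strand and perfect match", {
  te <- te_df("chr1", 1000, 7000, strand = "+", is_fli = TRUE)
  lib <- libs_for("s1", 1e6)
  reads <- rbind(
    aln("anti", 2000, strand = "-", read_length = 28),
    aln("mm", 2100, strand = "-", read_length = 28, mismatches = 1L),
    aln("sense", 2200, strand = "+", read_length = 28),
    aln("short", 2300, strand = "-", read_length = 20, end = 2320),
    aln("off", 9000, strand = "-", read_length = 28))
  prof <- antisense_length_profile(reads, te, lib)
  expect_equal(prof$rpm[prof$length == 28], 1)
  expect_equal(sum(prof$rpm), 1)
  ## with mismatches allowed, the 1-mismatch read is admitted
  loose <- antisense_length_profile(reads, te, lib, perfect_only = FALSE)
  expect_equal(loose$rpm[loose$length == 28], 2)
  expect_error(antisense_length_profile(reads, te[0, ], lib), "empty")
})

test_that("antisense profiles are invariant under flipping every strand", {
  set.seed(23)
  te <- te_df("chr1", start = c(0, 10000), end = c(5000, 15000),
              strand = c("+", "-"))
  reads <- do.call(rbind, lapply(1:80, function(i) {
    s <- sample(0:14000, 1)
    aln(paste0("r", i), s, end = s + 28,
        strand = sample(c("+", "-"), 1),
        mismatches = sample(0:1, 1))
  }))
  lib <- libs_for("s1", 1e6)
  flip <- function(x) ifelse(x == "+", "-", "+")
  a <- antisense_length_profile(reads, te, lib)
  reads2 <- reads; reads2$strand <- flip(reads$strand)
  te2 <- te; te2$strand <- flip(te$strand)
  b <- antisense_length_profile(reads2, te2, lib)
  expect_equal(a, b)
})

test_that("upregulation ranking sorts by fold change with stable tie-breaks", {
  wt <- c(MYSERV6 = 10, IAP = 50, L1 = 20, ZERO = 0)
  ko <- c(MYSERV6 = 33, IAP = 100, L1 = 20, ZERO = 5)
  rk <- rank_upregulated(wt[1:3], ko[1:3], pseudocount = 0)
  expect_equal(rk$group[1], "MYSERV6")
  expect_equal(rk$fold_change[rk$group == "MYSERV6"], 3.3)
  rk2 <- rank_upregulated(wt, ko, pseudocount = 0.1)
  expect_true(rk2$wt_zero[rk2$group == "ZERO"])
  expect_equal(rk2$fold_change[rk2$group == "ZERO"], 51)
  ## all equal -> fold 1, tie-break by KO RPM then name
  flat_wt <- c(b = 5, a = 5, c = 7)
  flat_ko <- c(b = 5, a = 5, c = 7)
  rkf <- rank_upregulated(flat_wt, flat_ko, pseudocount = 0.1)
  expect_equal(rkf$group, c("c", "a", "b"))
  ## invariant to input order
  perm <- rank_upregulated(wt[c(3, 1, 4, 2)], ko[c(2, 4, 1, 3)])
  expect_equal(perm, rank_upregulated(wt, ko))
  expect_error(rank_upregulated(wt, ko[1:3]), "universes")
})

test_that("divergence summaries match direct quantile computation", {
  te <- te_df("chr1", start = c(0, 100, 200), end = c(50, 150, 250),
              subfamily = "X", milli_div = c(10, 20, 30))
  ds <- divergence_summary(te)
  expect_equal(ds$median, 2)
  expect_equal(ds$q1, 1.5)
  expect_equal(ds$q3, 2.5)

  single <- divergence_summary(te_df("chr1", 0, 50, milli_div = 40))
  expect_equal(unlist(single[c("median", "q1", "q3", "whisker_low",
                               "whisker_high")]),
               c(median = 4, q1 = 4, q3 = 4, whisker_low = 4,
                 whisker_high = 4))

  same <- divergence_summary(te_df("chr1", c(0, 100), c(50, 150),
                                   milli_div = c(25, 25)))
  expect_equal(same$whisker_low, 2.5)
  expect_equal(same$whisker_high, 2.5)

  set.seed(27)
  for (i in 1:10) {
    n <- sample(3:60, 1)
    div <- round(runif(n, 5, 400))
    ds2 <- divergence_summary(te_df("chr1", seq_len(n) * 100,
                                    seq_len(n) * 100 + 50,
                                    milli_div = div))
    x <- div / 10
    q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    expect_equal(ds2$q1, q[1])
    expect_equal(ds2$median, q[2])
    expect_equal(ds2$q3, q[3])
    expect_equal(ds2$whisker_low, min(x[x >= q[1] - 1.5 * iqr]))
    expect_equal(ds2$whisker_high, max(x[x <= q[3] + 1.5 * iqr]))
    expect_true(ds2$q1 <= ds2$median && ds2$median <= ds2$q3)
  }
})

test_that("FLI flags are attached from the BED subset", {
  te <- rbind(te_df("chr1", 0, 5000), te_df("chr1", 10000, 15000))
  fli <- data.frame(chrom = "chr1", start = 10000, end = 15000)
  marked <- mark_fli(te, fli)
  expect_equal(marked$is_fli, c(FALSE, TRUE))
})
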