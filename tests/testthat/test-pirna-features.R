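test_that("library stats count distinct reads and miRNA assignments", {
  reads <- rbind(
    aln("a", 100, read_length = 28),
    aln("a", 500, read_length = 28, is_primary = FALSE, n_hits = 2L),
    aln("b", 200, read_length = 18),
    aln("c", 300, read_length = 22),
    aln("d", 400, read_length = 33))
  lib <- library_stats(reads, "s1")
  expect_equal(lib$total_19_32, 2)     # a (28) and c (22); multimapper once
  expect_equal(lib$total_18_32, 3)
  expect_equal(lib$mirna_count, 1)     # proxy: 21-23 nt

  mirna <- data.frame(chrom = "chr1", start = 95, end = 130)
  lib2 <- library_stats(reads, "s1", mirna = mirna)
  expect_equal(lib2$mirna_count, 1)    # annotation route: read a only
})

test_that("length profiles count each read once and conserve totals", {
  reads <- rbind(aln("x", 0, read_length = 29),
                 aln("y", 100, read_length = 29),
                 aln("z", 200, read_length = 30),
                 aln("m", 300, read_length = 29, n_hits = 5L),
                 aln("m", 400, read_length = 29, n_hits = 5L,
                     is_primary = FALSE))
  lib <- libs_for("s1", 1e6)
  prof <- length_profile(reads, lib)
  expect_equal(prof$rpm[prof$length == 29], 3)  # m counted once
  expect_equal(prof$rpm[prof$length == 30], 1)
  ## conservation: sum x denominator / 1e6 = distinct in-range reads
  expect_equal(sum(prof$rpm) * 1e6 / 1e6, 4)

  empty <- length_profile(empty_aln(), lib)
  expect_true(all(empty$rpm == 0))
  expect_error(length_profile(reads, libs_for("s1", 0)), "positive")
})

test_that("size classes sum their inclusive bins", {
  prof <- data.frame(length = 18:32, rpm = 0)
  prof$rpm[prof$length %in% c(19, 20)] <- 5
  prof$rpm[prof$length == 22] <- 7
  prof$rpm[prof$length == 26] <- 1
  prof$rpm[prof$length == 30] <- 2
  sc <- size_class_summary(prof)
  expect_equal(sc$rpm, c(10, 7, 1, 2))
  expect_equal(sum(sc$rpm), sum(prof$rpm[prof$length <= 31]))
  all0 <- size_class_summary(data.frame(length = 18:32, rpm = 0))
  expect_true(all(all0$rpm == 0))
})

test_that("miRNA scaling factor equalizes miRNA RPM across genotypes", {
  wt <- data.frame(sample_id = c("w1", "w2"),
                   total_19_32 = c(1e6, 1e6), total_18_32 = c(1e6, 1e6),
                   mirna_count = c(180000, 220000))
  ko <- data.frame(sample_id = "k", total_19_32 = 1e6, total_18_32 = 1e6,
                   mirna_count = 100000)
  expect_equal(mirna_scaling_factor(ko, wt), 2)
  expect_equal(mirna_scaling_factor(wt[1, ], wt[1, ]), 1)

  ## identity: after scaling, KO miRNA RPM equals the WT mean exactly
  set.seed(11)
  for (i in 1:10) {
    wt2 <- data.frame(sample_id = c("w1", "w2"),
                      total_19_32 = sample(1e5:1e6, 2),
                      total_18_32 = sample(1e5:1e6, 2),
                      mirna_count = sample(1e4:1e5, 2))
    ko2 <- data.frame(sample_id = "k", total_19_32 = sample(1e5:1e6, 1),
                      total_18_32 = 1e6, mirna_count = sample(1e4:1e5, 1))
    f <- mirna_scaling_factor(ko2, wt2)
    ko_rpm <- ko2$mirna_count * 1e6 / ko2$total_19_32
    wt_rpm <- mean(wt2$mirna_count * 1e6 / wt2$total_19_32)
    expect_equal(ko_rpm * f, wt_rpm, tolerance = 1e-12)
  }
  ko0 <- ko; ko0$mirna_count <- 0
  expect_error(mirna_scaling_factor(ko0, wt), "zero miRNA")
})

test_that("logo selection equals the conjunction of its four predicates", {
  clusters <- data.frame(chrom = "chr1", start = 1000, end = 3000)
  set.seed(21)
  n <- 300
  reads <- do.call(rbind, lapply(seq_len(n), function(i) {
    L <- sample(22:33, 1)
    p5 <- sample(0:4000, 1)
    aln(paste0("r", i), p5, end = p5 + L, read_length = L,
        is_primary = sample(c(TRUE, FALSE), 1),
        clipped5 = sample(c(TRUE, FALSE), 1, prob = c(0.2, 0.8)),
        sequence = paste(sample(c("A", "C", "G", "T"), L, TRUE),
                         collapse = ""))
  }))
  got <- select_logo_reads(reads, clusters)
  want <- reads[reads$is_primary & !reads$clipped5 &
                  reads$read_length >= 25 & reads$read_length <= 31 &
                  reads$start >= 1000 & reads$start < 3000, ]
  expect_equal(sort(got), sort(chartr("T", "U", want$sequence)))
})

test_that("logo selection drops clipped, secondary and out-of-range reads", {
  clusters <- data.frame(chrom = "chr1", start = 0, end = 10000)
  base <- function(id, ...) aln(id, 100, read_length = 27, end = 127,
                                sequence = strrep("ACG", 9), ...)
  expect_length(select_logo_reads(base("ok"), clusters), 1)
  expect_length(select_logo_reads(base("clip", clipped5 = TRUE), clusters), 0)
  expect_length(select_logo_reads(base("sec", is_primary = FALSE), clusters), 0)
  short <- aln("short", 100, read_length = 24, end = 124,
               sequence = strrep("ACGT", 6))
  expect_length(select_logo_reads(short, clusters), 0)
  outside <- base("out")
  outside$start <- 20000; outside$end <- 20027
  expect_length(select_logo_reads(outside, clusters), 0)
  noseq <- aln("noseq", 100, read_length = 27, end = 127)
  expect_error(select_logo_reads(noseq, clusters), "without sequence")
})

test_that("position frequencies are normalized, N-aware and T->U mapped", {
  pfm <- position_frequencies(c("UAAG", "UGGC", "AGGC"))
  expect_equal(unname(pfm[1, "U"]), 2 / 3)
  expect_true(all(abs(rowSums(pfm) - 1) < 1e-9))

  one <- position_frequencies(strrep("A", 12))
  expect_equal(bias_stats(one)$a10_fraction, 1)

  withN <- position_frequencies(c("NA", "AA"))   # N excluded at position 1
  expect_equal(unname(withN[1, "A"]), 1)

  dna <- position_frequencies(c("TTT", "TTT"))
  expect_equal(unname(dna[1, "U"]), 1)

  ## variable lengths: position 3 only covered by the longer sequence
  var <- position_frequencies(c("AC", "ACG"))
  expect_equal(unname(var[3, "G"]), 1)

  expect_error(position_frequencies(character()), "no sequences")
})

test_that("bias statistics recover planted probabilities on random sequences", {
  set.seed(31)
  n <- 5000
  u1 <- 0.7; a10 <- 0.4
  seqs <- vapply(seq_len(n), function(i) {
    L <- sample(25:31, 1)
    s <- sample(c("A", "C", "G", "U"), L, TRUE)
    s[1] <- if (runif(1) < u1) "U" else sample(c("A", "C", "G"), 1)
    s[10] <- if (runif(1) < a10) "A" else sample(c("C", "G", "U"), 1)
    paste(s, collapse = "")
  }, "")
  b <- bias_stats(position_frequencies(seqs))
  expect_lt(abs(b$u1_fraction - u1), 3 * sqrt(u1 * (1 - u1) / n))
  expect_lt(abs(b$a10_fraction - a10), 3 * sqrt(a10 * (1 - a10) / n))
})
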