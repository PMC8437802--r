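## Independent brute-force enumeration of the windowed classification rules
## (plain loops; shares no code with the package implementation).
oracle_testes <- function(reads_by_sample, chrom_len, gaps, libs, design,
                          rpkm_min = 1, threshold = -2, pseudo = 0.01,
                          max_gap = 2000, pre_min = 10, pach_min = 100) {
  n_win <- ceiling(chrom_len / 1000)
  win_start <- (seq_len(n_win) - 1) * 1000
  win_end <- pmin(win_start + 1000, chrom_len)
  ov <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))
  eff <- win_end - win_start
  for (g in seq_len(nrow(gaps)))
    for (k in seq_len(n_win))
      eff[k] <- eff[k] - ov(win_start[k], win_end[k], gaps$start[g], gaps$end[g])
  samples <- design$sample_id
  tot <- setNames(libs$total_19_32, libs$sample_id)[samples]
  counts <- matrix(0, n_win, length(samples), dimnames = list(NULL, samples))
  for (s in samples) {
    r <- reads_by_sample[[s]]
    for (j in seq_len(nrow(r))) {
      if (r$read_length[j] < 24 || r$read_length[j] > 31) next
      p5 <- if (r$strand[j] == "+") r$start[j] else r$end[j] - 1
      counts[p5 %/% 1000 + 1, s] <- counts[p5 %/% 1000 + 1, s] + 1 / r$n_hits[j]
    }
  }
  rpm <- sweep(counts, 2, 1e6 / tot, `*`)
  keep_eff <- eff > 0
  rpkm <- rpm[keep_eff, , drop = FALSE] / (eff[keep_eff] / 1000)
  ws <- win_start[keep_eff]; we <- win_end[keep_eff]
  wt <- design$sample_id[design$genotype == "WT"]
  keep <- apply(rpkm[, wt, drop = FALSE] >= rpkm_min, 1, any)
  rpkm <- rpkm[keep, , drop = FALSE]; ws <- ws[keep]; we <- we[keep]
  cm <- function(g, tp) {
    ids <- design$sample_id[design$genotype == g & design$timepoint == tp]
    rowMeans(rpkm[, ids, drop = FALSE])
  }
  lfc <- function(tp) log2((cm("KO", tp) + pseudo) / (cm("WT", tp) + pseudo))
  l9 <- lfc("9dpp"); l13 <- lfc("13dpp"); l21 <- lfc("21dpp")
  stage <- rep(NA_character_, length(ws))
  stage[l9 < threshold & l13 < threshold] <- "pre_pachytene"
  stage[l21 < threshold & l13 > threshold] <- "pachytene"
  lab <- which(!is.na(stage))
  clusters <- list()
  for (i in lab) {
    k <- length(clusters)
    if (k > 0 && clusters[[k]]$end == ws[i] && clusters[[k]]$stage == stage[i]) {
      clusters[[k]]$end <- we[i]
      clusters[[k]]$n <- clusters[[k]]$n + 1L
    } else {
      clusters[[k + 1]] <- list(start = ws[i], end = we[i], stage = stage[i],
                                n = 1L)
    }
  }
  ## superclusters per stage
  out <- list()
  for (st in c("pre_pachytene", "pachytene")) {
    cs <- Filter(function(c) c$stage == st, clusters)
    for (c in cs) {
      k <- length(out)
      if (k > 0 && out[[k]]$stage == st && c$start - out[[k]]$end <= max_gap) {
        out[[k]]$end <- c$end
        out[[k]]$n <- out[[k]]$n + c$n
      } else out[[k + 1]] <- c
    }
  }
  ## finalize + density filter
  final <- list()
  for (c in out) {
    eff_len <- c$end - c$start
    for (g in seq_len(nrow(gaps)))
      eff_len <- eff_len - ov(c$start, c$end, gaps$start[g], gaps$end[g])
    if (eff_len <= 0) next
    rpms <- setNames(numeric(length(samples)), samples)
    for (s in samples) {
      r <- reads_by_sample[[s]]
      for (j in seq_len(nrow(r))) {
        if (r$read_length[j] < 24 || r$read_length[j] > 31) next
        p5 <- if (r$strand[j] == "+") r$start[j] else r$end[j] - 1
        if (p5 >= c$start && p5 < c$end)
          rpms[s] <- rpms[s] + (1 / r$n_hits[j]) * 1e6 / tot[s]
      }
    }
    wt_mean <- function(tp) {
      ids <- design$sample_id[design$genotype == "WT" & design$timepoint == tp]
      mean(rpms[ids])
    }
    wt_rpm <- if (c$stage == "pre_pachytene")
      (wt_mean("9dpp") + wt_mean("13dpp")) / 2 else wt_mean("21dpp")
    density <- wt_rpm / (eff_len / 1000)
    thr <- if (c$stage == "pre_pachytene") pre_min else pach_min
    if (density > thr)
      final[[length(final) + 1]] <-
        data.frame(chrom = "chr1", start = c$start, end = c$end,
                   stage = c$stage, n_windows = c$n, density = density,
                   stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, final)
  if (is.null(df))
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     stage = character(), n_windows = integer(),
                     density = numeric(), stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$stage), , drop = FALSE]
}

random_instance <- function() {
  n_win <- sample(5:100, 1)
  chrom_len <- n_win * 1000 - sample(0:999, 1)
  n_gaps <- sample(0:2, 1)
  gaps <- if (n_gaps > 0) {
    gs <- sort(sample(seq(0, chrom_len - 600, by = 500), n_gaps))
    data.frame(chrom = "chr1", start = gs, end = gs + sample(200:500, n_gaps, TRUE))
  } else data.frame(chrom = character(), start = numeric(), end = numeric())
  design <- design6()
  n_reads <- sample(20:200, 1)
  owner <- sample(design$sample_id, n_reads, TRUE,
                  prob = c(3, 3, 3, 1, 1, 1))  # WT-heavy so clusters form
  reads <- setNames(lapply(design$sample_id, function(s) {
    idx <- which(owner == s)
    if (!length(idx)) return(empty_aln())
    do.call(rbind, lapply(seq_along(idx), function(j) {
      L <- sample(20:33, 1)
      ## concentrate reads so that adjacent windows light up
      p5 <- min(max(0, round(stats::rnorm(1, mean = chrom_len * 0.3,
                                          sd = chrom_len * 0.15))),
                chrom_len - 1)
      strand <- sample(c("+", "-"), 1)
      s0 <- if (strand == "+") p5 else p5 - L + 1
      if (s0 < 0) { s0 <- 0; strand <- "+" }
      aln(sprintf("%s_r%d", s, j), s0, end = s0 + L, read_length = L,
          strand = strand, n_hits = sample(c(1L, 1L, 2L, 4L), 1))
    }))
  }), design$sample_id)
  libs <- libs_for(design$sample_id, sample(500:5000, 6))
  list(chrom_len = chrom_len, gaps = gaps, reads = reads, libs = libs,
       design = design)
}

run_both <- function(inst, pre_min, pach_min) {
  gm <- genome_model("chr1", inst$chrom_len,
                     gaps = if (nrow(inst$gaps)) inst$gaps else NULL)
  got <- suppressWarnings(call_testes_clusters(
    inst$reads, gm, inst$design, inst$libs,
    prepachytene_min = pre_min, pachytene_min = pach_min))$clusters
  want <- oracle_testes(inst$reads, inst$chrom_len, inst$gaps, inst$libs,
                        inst$design, pre_min = pre_min, pach_min = pach_min)
  list(got = got, want = want)
}
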