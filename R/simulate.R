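## Synthetic small-RNA alignment generator with planted ground truth.
##
## Emulates the statistical structure of knockout/wild-type small-RNA-seq
## libraries over a toy genome: stage-specific piRNA clusters lost in the
## knockout, multimapping reads, stage-typical length distributions, 5'-U and
## position-10-A sequence biases, TE-derived sense/antisense reads with
## planted KO/WT fold changes, miRNA loci at 21-23 nt and dense background
## loci that fill the library to realistic totals. Fully deterministic under
## (seed, config).

#' Build a simulation configuration
#'
#' See [sim_config_testes()] and [sim_config_oocyte()] for the two shipped
#' configurations; this constructor validates an arbitrary one.
#'
#' @param seed integer RNG seed (< 2^31).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size analysis window size (bp).
#' @param gap_fraction fraction of each chromosome covered by assembly-gap
#'   intervals of `gap_unit` bp, placed away from planted elements.
#' @param gap_unit length of one gap interval (bp).
#' @param clusters data.frame of planted clusters: `chrom`, `start`, `end`,
#'   `stage` (`pre_pachytene`/`pachytene`/`oocyte`), `strand`,
#'   `wt_rpm_per_kb` (nominal wild-type expression density), `ko_retention`
#'   (fraction of wild-type expression kept in the knockout, 0-1) and, for
#'   oocyte clusters, `ip1_rpm_per_kb`/`ip3_rpm_per_kb` (PIWIL1/PIWIL3 IP
#'   densities).
#' @param length_dist named list of per-population read-length distributions
#'   (named numeric probability vectors, names = lengths in nt); keys are
#'   stages plus `ip_piwil1`, `ip_piwil3`, `te`, `background` as needed.
#' @param u1_prob probability of U (T in DNA alphabet) at read position 1 of
#'   cluster-derived reads.
#' @param a10_prob probability of A at read position 10.
#' @param clip5_rate fraction of cluster reads emitted with a 1-nt 5' soft
#'   clip (unique mappers only).
#' @param multimap_rate fraction of cluster/TE reads that multimap.
#' @param max_hits maximum `n_hits` of a multimapper.
#' @param te data.frame of TE subfamilies: `subfamily`, `group`, `class`,
#'   `n_insertions`, `len_min`, `len_max`, `div_mean` (milli_div),
#'   `wt_rpm`, `ko_fold`, `antisense_frac`, `fli_fraction`.
#' @param te_mismatch_rate fraction of sense TE reads with >= 1 mismatch
#'   (antisense TE reads are always perfect matches).
#' @param mirna_n_loci miRNA loci per chromosome.
#' @param mirna_rpm nominal miRNA read rate (RPM), single value or named by
#'   genotype.
#' @param background_n_loci background expressed loci per chromosome.
#' @param background_locus_len length of one background locus (bp).
#' @param background_rpm nominal background rate (RPM), single or named by
#'   genotype; set 0 for a noiseless library.
#' @param depth nominal reads per sample.
#' @param design data.frame: `sample_id`, `genotype` (`WT`/`KO`),
#'   `timepoint` (`9dpp`/`13dpp`/`21dpp` or `NA`), `role` (`testes`,
#'   `oocyte`, `ip_piwil1`, `ip_piwil3`).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed, chrom_lengths, window_size, gap_fraction,
                       gap_unit, clusters, length_dist, u1_prob, a10_prob,
                       clip5_rate, multimap_rate, max_hits, te,
                       te_mismatch_rate, mirna_n_loci, mirna_rpm,
                       background_n_loci, background_locus_len,
                       background_rpm, depth, design) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  probs <- c(gap_fraction, u1_prob, a10_prob, clip5_rate, multimap_rate,
             te_mismatch_rate, clusters$ko_retention, te$fli_fraction,
             te$antisense_frac)
  if (any(probs < 0 | probs > 1))
    stop("probabilities/fractions must lie in [0, 1]", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (max_hits < 1) stop("max_hits must be >= 1", call. = FALSE)
  cl <- clusters
  len <- chrom_lengths[cl$chrom]
  if (anyNA(len) || any(cl$start < 0) || any(cl$end > len))
    stop("planted cluster outside chromosome bounds", call. = FALSE)
  check_intervals(cl$start, cl$end, "planted cluster")
  for (d in length_dist)
    if (abs(sum(d) - 1) > 1e-8)
      stop("length distribution does not sum to 1", call. = FALSE)
  stopifnot(all(c("sample_id", "genotype", "role") %in% names(design)))
  cfg
}

## rate lookup: named vectors may key by sample role (ip_piwil1, oocyte, ...)
## or genotype (WT/KO); role wins, unnamed scalars apply to every sample
rate_for <- function(x, genotype, role = NULL) {
  if (is.null(names(x))) return(unname(x[1]))
  if (!is.null(role) && role %in% names(x)) return(unname(x[[role]]))
  if (genotype %in% names(x)) return(unname(x[[genotype]]))
  unname(x[[1]])
}

#' Shipped "hamster-like" testes configuration
#'
#' The noiseless end-to-end validation condition: two 1-Mb chromosomes tiled
#' at 1 kb, six planted clusters (three supra-threshold pre-pachytene, two
#' pachytene, one pre-pachytene decoy at 3 RPM/kb, below the 10 RPM/kb
#' density cutoff), complete knockout loss (`ko_retention = 0`), 1U/10A
#' probabilities 0.8/0.5, three LTR retrotransposon subfamilies (MYSERV6,
#' MYSERV, IAP, with an IAP FLI subset) with knockout fold increases of 20x,
#' 3.3x and 2x, and a WT/KO x {9, 13, 21} d.p.p. x 2 replicate design at
#' 200,000 reads per library. Every read is drawn from a planted element
#' (clusters, TE insertions, miRNA loci or dense background loci), so
#' cluster recovery is exact.
#'
#' @param seed RNG seed.
#' @param depth reads per library.
#' @return a [sim_config()].
#' @export
sim_config_testes <- function(seed = 1, depth = 2e5) {
  clusters <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr2"),
    start = c(100000, 300000, 150000, 600000, 500000, 800000),
    end   = c(103000, 302000, 154000, 602000, 503000, 802000),
    stage = c("pre_pachytene", "pre_pachytene", "pre_pachytene",
              "pachytene", "pachytene", "pre_pachytene"),
    strand = c("+", "-", "+", "+", "-", "+"),
    wt_rpm_per_kb = c(40, 80, 60, 200, 300, 3),
    ko_retention = 0,
    name = c("preA", "preB", "preC", "pachA", "pachB", "decoy"),
    stringsAsFactors = FALSE)
  te <- data.frame(
    subfamily = c("MYSERV6-int", "MYSERV-int", "IAPEz-int"),
    group = c("MYSERV6", "MYSERV", "IAP"),
    class = "LTR",
    n_insertions = 15,
    len_min = c(2000, 2000, 4000),
    len_max = c(4000, 4000, 7000),
    div_mean = c(15, 40, 30),
    wt_rpm = c(200, 300, 500),
    ko_fold = c(20, 3.3, 2),
    antisense_frac = c(0.5, 0.4, 0.5),
    fli_fraction = c(0, 0, 0.4),
    stringsAsFactors = FALSE)
  design <- expand.grid(genotype = c("WT", "KO"),
                        timepoint = c("9dpp", "13dpp", "21dpp"),
                        rep = 1:2, stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_r%d", tolower(design$genotype),
                              sub("dpp", "", design$timepoint), design$rep)
  design$role <- "testes"
  sim_config(
    seed = seed,
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    window_size = 1000, gap_fraction = 0.02, gap_unit = 1000,
    clusters = clusters,
    length_dist = list(
      pre_pachytene = c("24" = 0.04, "25" = 0.08, "26" = 0.14, "27" = 0.22,
                        "28" = 0.22, "29" = 0.14, "30" = 0.10, "31" = 0.06),
      pachytene = c("24" = 0.02, "25" = 0.04, "26" = 0.06, "27" = 0.10,
                    "28" = 0.16, "29" = 0.26, "30" = 0.24, "31" = 0.12),
      te = c("24" = 0.06, "25" = 0.10, "26" = 0.16, "27" = 0.20, "28" = 0.18,
             "29" = 0.14, "30" = 0.10, "31" = 0.04, "32" = 0.02),
      background = setNames(rep(1 / 15, 15), 18:32)),
    u1_prob = 0.8, a10_prob = 0.5, clip5_rate = 0.02,
    multimap_rate = 0.15, max_hits = 4,
    te = te, te_mismatch_rate = 0.3,
    mirna_n_loci = 12, mirna_rpm = 150000,
    background_n_loci = 20, background_locus_len = 2000,
    background_rpm = 700000,
    depth = depth,
    design = design[, c("sample_id", "genotype", "timepoint", "role")])
}

#' Shipped oocyte configuration
#'
#' One 500-kb chromosome with four planted oocyte clusters: one strong in
#' both PIWI IPs, one PIWIL3-only, one PIWIL1-only and one decoy that is
#' IP-positive but falls below the 10-RPM combined 18-20 + 24-32-nt
#' wild-type filter. Samples: one PIWIL1 IP, one PIWIL3 IP and WT/KO oocyte
#' total small-RNA libraries in duplicate; knockout oocytes retain 5% of
#' cluster piRNAs (a massive but incomplete loss) while the absolute miRNA
#' rate is genotype-independent, which is what miRNA rescaling exploits.
#'
#' @param seed RNG seed.
#' @param depth reads per library.
#' @return a [sim_config()].
#' @export
sim_config_oocyte <- function(seed = 1, depth = 2e5) {
  clusters <- data.frame(
    chrom = "chr1",
    start = c(50000, 150000, 300000, 420000),
    end   = c(53000, 152000, 303000, 421000),
    stage = "oocyte",
    strand = c("+", "-", "+", "+"),
    wt_rpm_per_kb = c(60, 40, 50, 1),
    ko_retention = 0.05,
    ip1_rpm_per_kb = c(150000, 800, 120000, 40000),
    ip3_rpm_per_kb = c(100000, 140000, 900, 30000),
    name = c("ooA", "ooB_piwil3", "ooC_piwil1", "oo_decoy"),
    stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = c("ip_piwil1", "ip_piwil3", "wt_oo_r1", "wt_oo_r2",
                  "ko_oo_r1", "ko_oo_r2"),
    genotype = c("WT", "WT", "WT", "WT", "KO", "KO"),
    timepoint = NA_character_,
    role = c("ip_piwil1", "ip_piwil3", rep("oocyte", 4)),
    stringsAsFactors = FALSE)
  sim_config(
    seed = seed,
    chrom_lengths = c(chr1 = 5e5),
    window_size = 1000, gap_fraction = 0.01, gap_unit = 1000,
    clusters = clusters,
    length_dist = list(
      oocyte = c(setNames(rep(0.25 / 3, 3), 18:20),
                 setNames(rep(0.15 / 3, 3), 21:23),
                 setNames(rep(0.60 / 9, 9), 24:32)),
      ip_piwil1 = c("27" = 0.15, "28" = 0.30, "29" = 0.35, "30" = 0.20),
      ip_piwil3 = c("18" = 0.25, "19" = 0.50, "20" = 0.25),
      te = c("24" = 0.1, "25" = 0.1, "26" = 0.2, "27" = 0.2, "28" = 0.2,
             "29" = 0.1, "30" = 0.1),
      background = setNames(rep(1 / 15, 15), 18:32)),
    u1_prob = 0.8, a10_prob = 0.5, clip5_rate = 0.02,
    multimap_rate = 0.1, max_hits = 4,
    te = data.frame(subfamily = "IAPEz-int", group = "IAP", class = "LTR",
                    n_insertions = 8, len_min = 4000, len_max = 6000,
                    div_mean = 30, wt_rpm = 8, ko_fold = 1.5,
                    antisense_frac = 0.5, fli_fraction = 0.4,
                    stringsAsFactors = FALSE),
    te_mismatch_rate = 0.3,
    mirna_n_loci = 12,
    mirna_rpm = c(WT = 200000, KO = 200000,
                  ip_piwil1 = 30000, ip_piwil3 = 30000),
    background_n_loci = 15, background_locus_len = 2000,
    background_rpm = c(WT = 500000, KO = 300000,
                       ip_piwil1 = 0, ip_piwil3 = 0),
    depth = depth,
    design = design)
}

## ---- genome simulation ----

## rejection-sampling interval allocator keeping placed elements apart
place_intervals <- function(n, len_min, len_max, chrom_lengths, occupied,
                            margin = 4500) {
  ## margin keeps distinct planted elements far enough apart that their
  ## 1-kb windows can never be bridged by the 2-kb supercluster step
  out <- vector("list", n)
  chroms <- names(chrom_lengths)
  for (i in seq_len(n)) {
    for (try in 1:2000) {
      cn <- chroms[sample.int(length(chroms), 1)]
      L <- if (len_max > len_min)
        len_min + sample.int(len_max - len_min, 1) else len_min
      s <- sample.int(chrom_lengths[[cn]] - L, 1) - 1
      cand <- IRanges::IRanges(s + 1 - margin, s + L + margin)
      occ <- occupied[[cn]]
      if (!length(occ) || !IRanges::overlapsAny(cand, occ)) {
        occupied[[cn]] <- c(occ, IRanges::IRanges(s + 1, s + L))
        out[[i]] <- data.frame(chrom = cn, start = s, end = s + L,
                               stringsAsFactors = FALSE)
        break
      }
      if (try == 2000) stop("could not place interval; genome too crowded",
                            call. = FALSE)
    }
  }
  list(intervals = do.call(rbind, out) %||%
         data.frame(chrom = character(), start = numeric(), end = numeric()),
       occupied = occupied)
}

#' Simulate the genome-side annotation of a configuration
#'
#' Places assembly gaps, TE insertions (with divergence values and the FLI
#' subset), miRNA loci and background expressed loci on the configured
#' chromosomes, all away from the planted clusters and from each other.
#' Deterministic under the caller's RNG state; [simulate_dataset()] seeds it.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([genome_model()] with gaps), `te` (TE record
#'   data.frame), `mirna` and `background` (interval data.frames).
#' @export
simulate_genome <- function(config) {
  cl <- config$clusters
  occupied <- lapply(config$chrom_lengths, function(...) IRanges::IRanges())
  for (i in seq_len(nrow(cl))) {
    cn <- cl$chrom[i]
    occupied[[cn]] <- c(occupied[[cn]],
                        IRanges::IRanges(cl$start[i] + 1 - 5000,
                                         cl$end[i] + 5000))
  }
  n_chrom <- length(config$chrom_lengths)
  ## TE insertions
  te_rows <- list()
  for (i in seq_len(nrow(config$te))) {
    row <- config$te[i, ]
    placed <- place_intervals(row$n_insertions, row$len_min, row$len_max,
                              config$chrom_lengths, occupied)
    occupied <- placed$occupied
    iv <- placed$intervals
    n <- nrow(iv)
    div <- rgamma(n, shape = 16, scale = row$div_mean / 16)
    te_rows[[i]] <- data.frame(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      strand = sample(c("+", "-"), n, TRUE),
      subfamily = row$subfamily, group = row$group, class = row$class,
      milli_div = round(pmax(div, 1)),
      is_fli = seq_len(n) <= round(row$fli_fraction * n),
      stringsAsFactors = FALSE)
  }
  te <- do.call(rbind, te_rows) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), subfamily = character(),
               group = character(), class = character(),
               milli_div = numeric(), is_fli = logical(),
               stringsAsFactors = FALSE)
  rownames(te) <- NULL
  ## miRNA loci (short, plus strand)
  placed <- place_intervals(config$mirna_n_loci * n_chrom, 30, 30,
                            config$chrom_lengths, occupied)
  occupied <- placed$occupied
  mirna <- placed$intervals
  if (nrow(mirna)) {
    mirna$name <- sprintf("mir-%d", seq_len(nrow(mirna)))
    mirna$score <- 0
    mirna$strand <- "+"
  }
  ## background expressed loci
  placed <- place_intervals(config$background_n_loci * n_chrom,
                            config$background_locus_len,
                            config$background_locus_len,
                            config$chrom_lengths, occupied)
  occupied <- placed$occupied
  background <- placed$intervals
  ## assembly gaps
  n_gaps <- round(config$gap_fraction * sum(config$chrom_lengths) /
                    config$gap_unit)
  placed <- place_intervals(n_gaps, config$gap_unit, config$gap_unit,
                            config$chrom_lengths, occupied)
  gaps <- placed$intervals
  genome <- genome_model(names(config$chrom_lengths),
                         unname(config$chrom_lengths),
                         gaps = if (nrow(gaps)) gaps else NULL)
  list(genome = genome, te = te, mirna = mirna, background = background)
}

## ---- read simulation ----

sample_lengths <- function(dist, n) {
  as.integer(sample(names(dist), n, TRUE, prob = dist))
}

## DNA-alphabet sequences with planted 1U(T)/10A biases
sim_pirna_sequences <- function(lens, u1_prob, a10_prob) {
  n <- length(lens)
  if (!n) return(character())
  L <- max(lens)
  M <- matrix(sample(c("A", "C", "G", "T"), n * L, TRUE), n, L)
  M[, 1] <- ifelse(runif(n) < u1_prob, "T", sample(c("A", "C", "G"), n, TRUE))
  if (L >= 10)
    M[, 10] <- ifelse(runif(n) < a10_prob, "A",
                      sample(c("C", "G", "T"), n, TRUE))
  vapply(seq_len(n), function(i) paste(M[i, seq_len(lens[i])], collapse = ""),
         "")
}

aln_df <- function(read_id = character(), chrom = character(),
                   start = numeric(), end = numeric(), strand = character(),
                   read_length = integer(), n_hits = integer(),
                   mismatches = integer(), is_primary = logical(),
                   clipped5 = logical(), sequence = character()) {
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, read_length = read_length, n_hits = n_hits,
             mismatches = mismatches, is_primary = is_primary,
             clipped5 = clipped5, sequence = sequence,
             stringsAsFactors = FALSE)
}

## reads from one planted cluster: 5' ends uniform inside the interval,
## multimapper secondaries also inside it (piRNA clusters are repeat-rich)
sim_cluster_reads <- function(cl, rate_rpm, config, dist, prefix) {
  n <- rpois(1, rate_rpm * config$depth / 1e6)
  if (n == 0) return(aln_df())
  lens <- sample_lengths(dist, n)
  seqs <- sim_pirna_sequences(lens, config$u1_prob, config$a10_prob)
  multi <- runif(n) < config$multimap_rate & config$max_hits >= 2
  clip <- !multi & runif(n) < config$clip5_rate
  hits <- ifelse(multi, 1L + sample.int(max(config$max_hits - 1L, 1L), n, TRUE), 1L)
  ## true 5' position; for clipped reads the aligned 5' is one base inward,
  ## kept inside the interval
  p5 <- cl$start + ifelse(clip, 1, 0) +
    floor(runif(n) * (cl$end - cl$start - ifelse(clip, 2, 0)))
  ids <- sprintf("%s%06d", prefix, seq_len(n))
  span <- lens - clip
  if (cl$strand == "+") {
    start <- p5 + clip
    end <- start + span
  } else {
    end <- p5 + 1 - clip
    start <- end - span
  }
  primary <- aln_df(read_id = ids, chrom = cl$chrom, start = start, end = end,
                    strand = cl$strand, read_length = lens, n_hits = hits,
                    mismatches = 0L, is_primary = TRUE, clipped5 = clip,
                    sequence = seqs)
  extra <- rep(seq_len(n), hits - 1)
  if (!length(extra)) return(primary)
  p2 <- cl$start + floor(runif(length(extra)) * (cl$end - cl$start))
  L2 <- lens[extra]
  if (cl$strand == "+") {
    s2 <- p2
    e2 <- p2 + L2
  } else {
    e2 <- p2 + 1
    s2 <- e2 - L2
  }
  secondary <- aln_df(read_id = ids[extra], chrom = cl$chrom, start = s2,
                      end = e2, strand = cl$strand, read_length = L2,
                      n_hits = hits[extra], mismatches = 0L,
                      is_primary = FALSE, clipped5 = FALSE,
                      sequence = seqs[extra])
  rbind(primary, secondary)
}

## reads over the insertions of one TE subfamily
sim_te_reads <- function(sub, rate_rpm, config, prefix) {
  n <- rpois(1, rate_rpm * config$depth / 1e6)
  if (n == 0) return(aln_df())
  dist <- config$length_dist$te
  lens <- sample_lengths(dist, n)
  anti <- runif(n) < sub$antisense_frac[1]
  mm <- ifelse(anti, 0L,
               sample(0:2, n, TRUE,
                      prob = c(1 - config$te_mismatch_rate,
                               0.8 * config$te_mismatch_rate,
                               0.2 * config$te_mismatch_rate)))
  multi <- runif(n) < config$multimap_rate & config$max_hits >= 2 &
    nrow(sub) > 1
  hits <- ifelse(multi, 1L + sample.int(max(config$max_hits - 1L, 1L), n, TRUE), 1L)
  ids <- sprintf("%s%06d", prefix, seq_len(n))
  read_of <- c(seq_len(n), rep(seq_len(n), hits - 1))
  is_primary <- c(rep(TRUE, n), rep(FALSE, sum(hits - 1)))
  ins <- sample.int(nrow(sub), length(read_of), TRUE)
  L <- lens[read_of]
  start <- sub$start[ins] +
    floor(runif(length(read_of)) * (sub$end[ins] - sub$start[ins] - L))
  strand <- ifelse(anti[read_of], ifelse(sub$strand[ins] == "+", "-", "+"),
                   sub$strand[ins])
  aln_df(read_id = ids[read_of], chrom = sub$chrom[ins], start = start,
         end = start + L, strand = strand, read_length = L,
         n_hits = hits[read_of], mismatches = mm[read_of],
         is_primary = is_primary, clipped5 = FALSE,
         sequence = NA_character_)
}

sim_locus_reads <- function(loci, rate_rpm, config, dist, prefix,
                            at_start = FALSE) {
  n <- rpois(1, rate_rpm * config$depth / 1e6)
  if (n == 0 || !nrow(loci)) return(aln_df())
  lens <- sample_lengths(dist, n)
  idx <- sample.int(nrow(loci), n, TRUE)
  width <- loci$end[idx] - loci$start[idx]
  offset <- if (at_start) sample(0:2, n, TRUE) else
    floor(runif(n) * pmax(width - lens, 1))
  start <- loci$start[idx] + offset
  strand <- if (at_start) rep("+", n) else sample(c("+", "-"), n, TRUE)
  aln_df(read_id = sprintf("%s%06d", prefix, seq_len(n)), chrom = loci$chrom[idx],
         start = start, end = start + lens, strand = strand,
         read_length = lens, n_hits = 1L, mismatches = 0L,
         is_primary = TRUE, clipped5 = FALSE, sequence = NA_character_)
}

## nominal cluster read rate (RPM) for one sample
cluster_rate <- function(cl, sample_row) {
  total <- cl$wt_rpm_per_kb * (cl$end - cl$start) / 1000
  role <- sample_row$role
  if (role == "ip_piwil1")
    return(if (cl$stage == "oocyte") cl$ip1_rpm_per_kb * (cl$end - cl$start) / 1000 else 0)
  if (role == "ip_piwil3")
    return(if (cl$stage == "oocyte") cl$ip3_rpm_per_kb * (cl$end - cl$start) / 1000 else 0)
  if (role == "oocyte") {
    if (cl$stage != "oocyte") return(0)
    return(if (sample_row$genotype == "WT") total else total * cl$ko_retention)
  }
  ## testes: stage-specific developmental activity
  active <- switch(cl$stage,
                   pre_pachytene = sample_row$timepoint %in% c("9dpp", "13dpp"),
                   pachytene = sample_row$timepoint == "21dpp",
                   FALSE)
  if (!active) return(0)
  if (sample_row$genotype == "WT") total else total * cl$ko_retention
}

#' Simulate one small-RNA library
#'
#' Draws the sample's reads from the planted elements at their configured
#' nominal RPM rates (component counts are Poisson at `rate x depth / 1e6`):
#' cluster piRNAs (stage- and genotype-dependent, with sequences carrying the
#' 1U/10A biases), TE sense/antisense reads with the group's knockout fold,
#' miRNA-locus reads at 21-23 nt and background-locus reads. Records are
#' sorted by chromosome and start. Deterministic: the RNG is seeded from
#' (config seed, sample index).
#'
#' @param config a [sim_config()].
#' @param sim_genome output of [simulate_genome()].
#' @param sample_id sample to simulate (must be in the design).
#' @return list with `reads` (alignment data.frame) and `lib` (one-row
#'   [library_stats()] computed against the simulated miRNA annotation).
#' @export
simulate_library <- function(config, sim_genome, sample_id) {
  i <- match(sample_id, config$design$sample_id)
  if (is.na(i)) stop("sample not in design: ", sample_id, call. = FALSE)
  set.seed(derive_seed(config$seed, i))
  row <- config$design[i, ]
  parts <- list()
  cl <- config$clusters
  for (k in seq_len(nrow(cl))) {
    rate <- cluster_rate(cl[k, ], row)
    dist_key <- switch(row$role, ip_piwil1 = "ip_piwil1",
                       ip_piwil3 = "ip_piwil3", cl$stage[k])
    if (rate > 0)
      parts[[length(parts) + 1]] <- sim_cluster_reads(
        cl[k, ], rate, config, config$length_dist[[dist_key]],
        prefix = sprintf("%s_c%d_", sample_id, k))
  }
  te <- sim_genome$te
  for (k in seq_len(nrow(config$te))) {
    row_te <- config$te[k, ]
    rate <- row_te$wt_rpm *
      (if (row$genotype == "KO") row_te$ko_fold else 1)
    sub <- te[te$subfamily == row_te$subfamily, , drop = FALSE]
    sub$antisense_frac <- row_te$antisense_frac
    parts[[length(parts) + 1]] <-
      sim_te_reads(sub, rate, config, prefix = sprintf("%s_t%d_", sample_id, k))
  }
  parts[[length(parts) + 1]] <- sim_locus_reads(
    sim_genome$mirna, rate_for(config$mirna_rpm, row$genotype, row$role),
    config, setNames(c(0.25, 0.5, 0.25), 21:23),
    prefix = paste0(sample_id, "_m_"), at_start = TRUE)
  parts[[length(parts) + 1]] <- sim_locus_reads(
    sim_genome$background,
    rate_for(config$background_rpm, row$genotype, row$role),
    config, config$length_dist$background, prefix = paste0(sample_id, "_b_"))
  reads <- do.call(rbind, parts)
  reads <- reads[order(reads$chrom, reads$start, reads$read_id), ]
  rownames(reads) <- NULL
  list(reads = reads,
       lib = library_stats(reads, sample_id, mirna = sim_genome$mirna))
}

#' Simulate a complete dataset with ground truth
#'
#' Seeds the RNG from the config, simulates the genome-side annotation and
#' every library of the design, and assembles machine-readable truth tables
#' (planted clusters with expected densities, per-group TE rates and folds,
#' planted bias parameters, per-sample library totals). A self-audit
#' recounts the emitted records against the truth and errors on mismatch.
#'
#' @param config a [sim_config()].
#' @return list: `config`, `genome`, `te`, `mirna`, `background`,
#'   `reads_by_sample`, `libs`, `truth`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  sg <- simulate_genome(config)
  samples <- config$design$sample_id
  sims <- lapply(samples, function(s) simulate_library(config, sg, s))
  reads_by_sample <- setNames(lapply(sims, `[[`, "reads"), samples)
  libs <- do.call(rbind, lapply(sims, `[[`, "lib"))
  rownames(libs) <- NULL
  truth <- list(
    clusters = cbind(config$clusters,
                     expected_density = config$clusters$wt_rpm_per_kb),
    te_groups = config$te[, c("subfamily", "group", "wt_rpm", "ko_fold")],
    bias = data.frame(u1_prob = config$u1_prob, a10_prob = config$a10_prob),
    libraries = data.frame(
      sample_id = samples,
      n_reads = vapply(reads_by_sample, function(r)
        length(unique(r$read_id)), 0),
      n_records = vapply(reads_by_sample, nrow, 0),
      row.names = NULL, stringsAsFactors = FALSE))
  truth$libraries <- merge(truth$libraries, libs, by = "sample_id",
                           sort = FALSE)
  audit_truth(reads_by_sample, truth)
  list(config = config, genome = sg$genome, te = sg$te, mirna = sg$mirna,
       background = sg$background, reads_by_sample = reads_by_sample,
       libs = libs, truth = truth)
}

## generator self-audit: the truth tables must recount the emitted reads
audit_truth <- function(reads_by_sample, truth) {
  for (i in seq_len(nrow(truth$libraries))) {
    s <- truth$libraries$sample_id[i]
    r <- reads_by_sample[[s]]
    if (nrow(r) != truth$libraries$n_records[i] ||
        length(unique(r$read_id)) != truth$libraries$n_reads[i])
      stop("truth self-audit failed for sample ", s, call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a simulated dataset to disk
#'
#' Emits chrom.sizes, gaps.bed, repeats.out (+ group_map.tsv and fli.bed),
#' mirna.bed, one alignment file per sample (tabular dialect, optionally
#' SAM) and the truth tables under `truth/`. After writing, the alignment
#' files are re-read and recounted against the truth (audit; hard error on
#' mismatch).
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created).
#' @param format `"tabular"` or `"sam"` for the per-sample alignments.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir, format = c("tabular", "sam")) {
  format <- match.arg(format)
  dir.create(file.path(dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_chrom_sizes(sim$genome, file.path(dir, "chrom.sizes"))
  write_bed(sim$genome$gaps, file.path(dir, "gaps.bed"))
  write_repeatmasker_out(sim$te, file.path(dir, "repeats.out"))
  write_bed(sim$te[sim$te$is_fli, c("chrom", "start", "end")],
            file.path(dir, "fli.bed"))
  gm <- unique(sim$te[, c("subfamily", "group", "class")])
  gm$is_active <- TRUE
  write.table(gm, file.path(dir, "group_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(sim$mirna))
    write_bed(sim$mirna, file.path(dir, "mirna.bed"))
  for (s in names(sim$reads_by_sample)) {
    f <- file.path(dir, "alignments",
                   paste0(s, if (format == "sam") ".sam" else ".tsv"))
    if (format == "sam")
      write_alignments_sam(sim$reads_by_sample[[s]], sim$genome, f)
    else write_alignments_tabular(sim$reads_by_sample[[s]], f)
  }
  write.table(sim$libs, file.path(dir, "library_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(sim$truth))
    write.table(sim$truth[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  ## audit the files as written
  for (s in names(sim$reads_by_sample)) {
    f <- file.path(dir, "alignments",
                   paste0(s, if (format == "sam") ".sam" else ".tsv"))
    n <- nrow(read_alignments(f, if (format == "sam") "sam" else "tabular"))
    if (n != sim$truth$libraries$n_records[
      sim$truth$libraries$sample_id == s])
      stop("written-file audit failed for sample ", s, call. = FALSE)
  }
  invisible(dir)
}

#' Subset reads whose 5' end falls inside a set of intervals
#'
#' Read-level: every alignment row of a read is kept when at least one of
#' its alignments has its 5' end inside an interval.
#'
#' @param reads alignment data.frame.
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return subset of `reads`.
#' @export
reads_in_intervals <- function(reads, intervals) {
  if (!nrow(reads) || !nrow(intervals)) return(reads[0, , drop = FALSE])
  p5 <- five_prime_pos(reads)
  rg <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(p5 + 1, width = 1))
  inside <- IRanges::overlapsAny(rg, as_granges(intervals))
  keep_ids <- unique(reads$read_id[inside])
  reads[reads$read_id %in% keep_ids, , drop = FALSE]
}
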