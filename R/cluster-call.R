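#' Log2 fold change of knockout over wild-type signal
#'
#' `log2((ko + pseudocount)/(wt + pseudocount))`. The pseudocount keeps the
#' statistic finite when knockout windows have zero signal (complete piRNA
#' loss must still classify as "lower than -2") while perturbing expressed
#' windows by at most `log2((x + p)/x)` for the smaller of the two values.
#'
#' @param ko,wt non-negative values (typically replicate-averaged RPKM).
#' @param pseudocount added to both numerator and denominator (default 0.01).
#' @return log2 fold change(s); antisymmetric: `lfc(a, b) == -lfc(b, a)`.
#' @export
log2_fold_change <- function(ko, wt, pseudocount = 0.01) {
  if (any(ko < 0) || any(wt < 0))
    stop("fold change inputs must be non-negative", call. = FALSE)
  log2((ko + pseudocount) / (wt + pseudocount))
}

TIMEPOINTS <- c("9dpp", "13dpp", "21dpp")

check_design <- function(design, samples) {
  need <- c("sample_id", "genotype", "timepoint")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!all(design$genotype %in% c("WT", "KO")))
    stop("genotype must be WT or KO", call. = FALSE)
  missing <- setdiff(samples, design$sample_id)
  if (length(missing))
    stop("sample(s) not in design: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(design)
}

## replicate-averaged per-window values for one genotype x timepoint
condition_mean <- function(table, design, genotype, timepoint) {
  ids <- design$sample_id[design$genotype == genotype &
                          design$timepoint == timepoint]
  ids <- intersect(ids, table$samples)
  if (!length(ids))
    stop(sprintf("no %s sample at %s in the table", genotype, timepoint),
         call. = FALSE)
  rowMeans(table$values[, match(ids, table$samples), drop = FALSE])
}

#' Per-window KO/WT log2 fold changes across time points
#'
#' RPKMs are averaged over replicate samples within each genotype x time
#' point before the fold change is taken.
#'
#' @param table [window_table()] in unit `RPKM`.
#' @param design data.frame mapping `sample_id` to `genotype` (`WT`/`KO`) and
#'   `timepoint` (`9dpp`, `13dpp`, `21dpp`).
#' @param pseudocount see [log2_fold_change()].
#' @return data.frame: the windows plus `lfc_9dpp`, `lfc_13dpp`, `lfc_21dpp`.
#' @export
stage_fold_changes <- function(table, design, pseudocount = 0.01) {
  stopifnot(inherits(table, "window_table"), table$unit == "RPKM")
  check_design(design, character())
  out <- table$windows
  for (tp in TIMEPOINTS) {
    out[[paste0("lfc_", tp)]] <- log2_fold_change(
      condition_mean(table, design, "KO", tp),
      condition_mean(table, design, "WT", tp), pseudocount)
  }
  out
}

#' Classify windows into piRNA stage labels
#'
#' Pre-pachytene: KO/WT log2 fold change lower than the threshold at both
#' 9 d.p.p. and 13 d.p.p. Pachytene: lower than the threshold at 21 d.p.p.
#' and higher than the threshold at 13 d.p.p. All inequalities are strict, so
#' a fold change exactly at the threshold satisfies neither rule.
#'
#' @param fc data.frame from [stage_fold_changes()].
#' @param threshold log2 fold-change threshold (default -2).
#' @return character vector per window: `"pre_pachytene"`, `"pachytene"` or
#'   `NA` (unclassified).
#' @export
classify_windows <- function(fc, threshold = -2) {
  pre <- fc$lfc_9dpp < threshold & fc$lfc_13dpp < threshold
  pach <- fc$lfc_21dpp < threshold & fc$lfc_13dpp > threshold
  ifelse(pre, "pre_pachytene", ifelse(pach, "pachytene", NA_character_))
}

#' Merge immediately adjacent same-stage windows into clusters
#'
#' Maximal runs of windows with `end == next start` on the same chromosome
#' and with the same stage label become one cluster; labels never mix, and a
#' gap left by a filtered window splits clusters (bridging is the supercluster
#' step's job).
#'
#' @param labeled data.frame with `chrom`, `start`, `end`, `stage` (windows
#'   with `NA` stage are dropped), sorted by chromosome then start.
#' @return data.frame of clusters: `chrom`, `start`, `end`, `stage`,
#'   `n_windows`.
#' @export
merge_adjacent <- function(labeled) {
  labeled <- labeled[!is.na(labeled$stage), , drop = FALSE]
  if (!nrow(labeled))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stage = character(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  ord <- order(labeled$chrom, labeled$start)
  if (!identical(ord, seq_len(nrow(labeled))))
    stop("windows must be sorted by chrom, start", call. = FALSE)
  n <- nrow(labeled)
  new_run <- c(TRUE, labeled$chrom[-1] != labeled$chrom[-n] |
                 labeled$stage[-1] != labeled$stage[-n] |
                 labeled$start[-1] != labeled$end[-n])
  grp <- cumsum(new_run)
  data.frame(
    chrom = as.character(tapply(labeled$chrom, grp, `[`, 1)),
    start = as.numeric(tapply(labeled$start, grp, min)),
    end = as.numeric(tapply(labeled$end, grp, max)),
    stage = as.character(tapply(labeled$stage, grp, `[`, 1)),
    n_windows = as.integer(tapply(labeled$start, grp, length)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge clusters into superclusters
#'
#' Same-stage clusters on the same chromosome whose gap is at most `max_gap`
#' bp (inclusive, "at most 2 kb apart") are merged transitively; the merged
#' interval spans from the first start to the last end. Input order is
#' irrelevant (sorted internally) and the operation is idempotent.
#'
#' @param clusters data.frame from [merge_adjacent()].
#' @param max_gap maximum inter-cluster gap in bp (default 2000).
#' @return data.frame of superclusters, same columns.
#' @export
merge_superclusters <- function(clusters, max_gap = 2000) {
  if (!nrow(clusters)) return(clusters)
  ord <- order(clusters$stage, clusters$chrom, clusters$start)
  cl <- clusters[ord, , drop = FALSE]
  n <- nrow(cl)
  new_run <- c(TRUE, cl$chrom[-1] != cl$chrom[-n] |
                 cl$stage[-1] != cl$stage[-n] |
                 (cl$start[-1] - cl$end[-n]) > max_gap)
  grp <- cumsum(new_run)
  out <- data.frame(
    chrom = as.character(tapply(cl$chrom, grp, `[`, 1)),
    start = as.numeric(tapply(cl$start, grp, min)),
    end = as.numeric(tapply(cl$end, grp, max)),
    stage = as.character(tapply(cl$stage, grp, `[`, 1)),
    n_windows = as.integer(tapply(cl$n_windows, grp, sum)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$chrom, out$start, out$stage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## gap-corrected length of arbitrary intervals
effective_interval_length <- function(intervals, genome) {
  eff <- intervals$end - intervals$start
  if (nrow(genome$gaps) && nrow(intervals)) {
    ig <- as_granges(intervals)
    gg <- as_granges(genome$gaps)
    hits <- GenomicRanges::findOverlaps(ig, gg)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(ig)[S4Vectors::queryHits(hits)],
        IRanges::ranges(gg)[S4Vectors::subjectHits(hits)]))
      gap_bp <- tapply(ov, S4Vectors::queryHits(hits), sum)
      idx <- as.integer(names(gap_bp))
      eff[idx] <- eff[idx] - as.numeric(gap_bp)
    }
  }
  eff
}

## fractional counts of size-selected alignments whose 5' end lies inside
## each interval
interval_fractional_counts <- function(reads, intervals, size_min, size_max) {
  counts <- numeric(nrow(intervals))
  if (!nrow(reads) || !nrow(intervals)) return(counts)
  keep <- reads$read_length >= size_min & reads$read_length <= size_max
  r <- reads[keep, , drop = FALSE]
  if (!nrow(r)) return(counts)
  p5 <- five_prime_pos(r)
  rg <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(p5 + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(rg, as_granges(intervals))
  if (!length(hits)) return(counts)
  w <- (1 / r$n_hits)[S4Vectors::queryHits(hits)]
  agg <- rowsum(w, group = S4Vectors::subjectHits(hits))
  counts[as.integer(rownames(agg))] <- agg[, 1]
  counts
}

#' Recompute final cluster RPKMs and piRNA densities
#'
#' For each merged interval the fractional count of size-selected reads whose
#' 5' end lies inside it is recomputed per sample, normalized to RPM by the
#' library total and to RPKM by the gap-corrected interval length. Density is
#' the replicate-averaged wild-type RPM of the stage-defining time points
#' (9 + 13 d.p.p. for pre-pachytene, 21 d.p.p. for pachytene) per effective
#' kilobase. The manual-curation step of the original analysis is replaced by
#' a declarative include/exclude table.
#'
#' @param clusters data.frame from [merge_superclusters()].
#' @param reads_by_sample named list of alignment data.frames.
#' @param genome [genome_model()] (for gap correction).
#' @param libs library stats (see [library_stats()]).
#' @param design sample design (see [stage_fold_changes()]).
#' @param size_min,size_max read-length bounds counted (defaults 24, 31).
#' @param denominator library total used for RPM.
#' @param curation optional data.frame (or TSV path) with columns `chrom`,
#'   `start`, `end`, `action` (`include`/`exclude`); excluded intervals are
#'   dropped (exact match), and if any include rows exist only those are kept.
#' @return cluster data.frame with `effective_length`, per-condition
#'   `rpkm_<genotype>_<timepoint>` columns, `wt_rpm` (defining time points)
#'   and `density` (RPM per effective kb). Fully gapped intervals are dropped
#'   with a warning.
#' @export
finalize_clusters <- function(clusters, reads_by_sample, genome, libs, design,
                              size_min = 24, size_max = 31,
                              denominator = "total_19_32", curation = NULL) {
  design <- check_design(design, names(reads_by_sample))
  cl <- clusters
  if (!nrow(cl)) return(empty_final_clusters(design))
  cl$effective_length <- effective_interval_length(cl, genome)
  gone <- cl$effective_length <= 0
  if (any(gone)) {
    warning(sum(gone), " fully gapped cluster(s) dropped", call. = FALSE)
    cl <- cl[!gone, , drop = FALSE]
    if (!nrow(cl)) return(empty_final_clusters(design))
  }
  samples <- names(reads_by_sample)
  rpm <- sapply(samples, function(s) {
    cnt <- interval_fractional_counts(reads_by_sample[[s]], cl,
                                      size_min, size_max)
    cnt * 1e6 / lib_total(libs, s, denominator)
  })
  rpm <- matrix(rpm, nrow = nrow(cl), dimnames = list(NULL, samples))
  kb <- cl$effective_length / 1000
  for (gt in c("WT", "KO")) for (tp in TIMEPOINTS) {
    ids <- intersect(design$sample_id[design$genotype == gt &
                                      design$timepoint == tp], samples)
    if (!length(ids)) next
    cl[[paste0("rpkm_", gt, "_", tp)]] <-
      rowMeans(rpm[, ids, drop = FALSE]) / kb
  }
  wt_rpm_tp <- function(tp) {
    ids <- intersect(design$sample_id[design$genotype == "WT" &
                                      design$timepoint == tp], samples)
    rowMeans(rpm[, ids, drop = FALSE])
  }
  cl$wt_rpm <- ifelse(cl$stage == "pre_pachytene",
                      (wt_rpm_tp("9dpp") + wt_rpm_tp("13dpp")) / 2,
                      wt_rpm_tp("21dpp"))
  cl$density <- cl$wt_rpm / kb
  rownames(cl) <- NULL
  apply_curation(cl, curation)
}

empty_final_clusters <- function(design) {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stage = character(), n_windows = integer(),
             effective_length = numeric(), wt_rpm = numeric(),
             density = numeric(), stringsAsFactors = FALSE)
}

apply_curation <- function(clusters, curation) {
  if (is.null(curation)) return(clusters)
  if (is.character(curation))
    curation <- read.table(curation, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "action") %in% names(curation)))
  key <- function(df) paste(df$chrom, df$start, df$end)
  inc <- curation[curation$action == "include", , drop = FALSE]
  exc <- curation[curation$action == "exclude", , drop = FALSE]
  keep <- rep(TRUE, nrow(clusters))
  if (nrow(inc)) keep <- key(clusters) %in% key(inc)
  if (nrow(exc)) keep <- keep & !(key(clusters) %in% key(exc))
  if (any(!keep))
    message(sum(!keep), " cluster(s) removed by curation list")
  clusters[keep, , drop = FALSE]
}

#' Retain clusters above stage-specific piRNA density thresholds
#'
#' Retention is strictly "greater than": a pre-pachytene cluster at exactly
#' 10 RPM/kb is removed. The pachytene threshold defaults to 100 RPM per
#' effective kilobase; set `pachytene_per_kb = FALSE` to read it as 100 RPM
#' total per cluster instead (the wording is elliptic; both supported).
#'
#' @param clusters data.frame from [finalize_clusters()].
#' @param prepachytene_min density threshold for pre-pachytene clusters
#'   (RPM/kb, default 10).
#' @param pachytene_min threshold for pachytene clusters (default 100).
#' @param pachytene_per_kb interpret `pachytene_min` per kilobase (default)
#'   or as total cluster RPM.
#' @return filtered cluster data.frame.
#' @export
filter_density <- function(clusters, prepachytene_min = 10,
                           pachytene_min = 100, pachytene_per_kb = TRUE) {
  if (!nrow(clusters)) return(clusters)
  pach_value <- if (pachytene_per_kb) clusters$density else clusters$wt_rpm
  keep <- ifelse(clusters$stage == "pre_pachytene",
                 clusters$density > prepachytene_min,
                 pach_value > pachytene_min)
  clusters[keep, , drop = FALSE]
}

#' Call testes piRNA clusters from knockout/wild-type libraries
#'
#' The full windowed pipeline: tile the genome into `window_size` windows,
#' fractionally count 24-31-nt alignments per window and sample, normalize
#' to RPM (per million distinct 19-32-nt reads) and to RPKM over
#' gap-corrected window length, remove windows below `rpkm_min` in every
#' wild-type sample, classify windows from replicate-averaged KO/WT log2
#' fold changes, merge adjacent same-stage windows, bridge clusters at most
#' `max_gap` apart into superclusters, recompute final interval RPKMs and
#' densities, and keep clusters above the stage-specific density thresholds.
#'
#' @param reads_by_sample named list of alignment data.frames.
#' @param genome [genome_model()].
#' @param design sample design (see [stage_fold_changes()]).
#' @param libs library stats; computed from the reads when `NULL`.
#' @param window_size window size in bp (default 1000).
#' @param size_min,size_max counted read lengths (defaults 24, 31).
#' @param rpkm_min window prefilter threshold (default 1).
#' @param lfc_threshold classification threshold (default -2).
#' @param pseudocount fold-change pseudocount (default 0.01 RPKM).
#' @param max_gap supercluster gap (default 2000 bp).
#' @param prepachytene_min,pachytene_min,pachytene_per_kb density filter, see
#'   [filter_density()].
#' @param curation optional curation table, see [finalize_clusters()].
#' @return list with `clusters` (final calls), `window_rpkm` (all windows),
#'   `fold_changes` (prefiltered windows with per-time-point lfc) and `libs`.
#' @export
call_testes_clusters <- function(reads_by_sample, genome, design, libs = NULL,
                                 window_size = 1000, size_min = 24,
                                 size_max = 31, rpkm_min = 1,
                                 lfc_threshold = -2, pseudocount = 0.01,
                                 max_gap = 2000, prepachytene_min = 10,
                                 pachytene_min = 100, pachytene_per_kb = TRUE,
                                 curation = NULL) {
  design <- check_design(design, names(reads_by_sample))
  if (is.null(libs))
    libs <- do.call(rbind, lapply(names(reads_by_sample), function(s)
      library_stats(reads_by_sample[[s]], s)))
  windows <- tile_genome(genome, window_size)
  counts <- fractional_count_samples(reads_by_sample, windows,
                                     size_min, size_max)
  rpkm <- to_rpkm(to_rpm(counts, libs))
  wt_ids <- intersect(design$sample_id[design$genotype == "WT"],
                      names(reads_by_sample))
  pre <- filter_min_rpkm(rpkm, rpkm_min, "any_sample", samples = wt_ids)
  fc <- stage_fold_changes(pre, design, pseudocount)
  fc$stage <- classify_windows(fc, lfc_threshold)
  clusters <- merge_adjacent(fc[, c("chrom", "start", "end", "stage")])
  clusters <- merge_superclusters(clusters, max_gap)
  final <- finalize_clusters(clusters, reads_by_sample, genome, libs, design,
                             size_min, size_max, curation = curation)
  final <- filter_density(final, prepachytene_min, pachytene_min,
                          pachytene_per_kb)
  rownames(final) <- NULL
  list(clusters = final, window_rpkm = rpkm, fold_changes = fc, libs = libs)
}
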