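## Retrotransposon-centric quantification: once-per-read group counting,
## antisense perfect-match length profiles, KO/WT ranking and RepeatMasker
## divergence summaries.

#' Count each read once per transposable-element group
#'
#' A read contributes exactly 1 to every distinct group (or subfamily) that
#' any of its alignments overlaps by at least one bp - hitting fifty
#' insertions of one subfamily still counts once, which is what makes
#' multimapper-rich TE expression summable. The default keeps a read
#' countable in several different groups (the once-per-read rule plainly
#' addresses within-group multimapping); `mode = "unique_global"` instead
#' assigns the read to the single group with the most alignment overlaps,
#' ties broken lexicographically.
#'
#' @param reads alignment data.frame.
#' @param te_records TE annotation data.frame (see
#'   [read_repeatmasker_out()]).
#' @param group_by count by curated `"group"` (default) or by
#'   `"subfamily"`.
#' @param mode `"per_group"` (default) or `"unique_global"`.
#' @return named numeric vector of distinct-read counts per group, covering
#'   every group present in `te_records` (zeros included).
#' @export
assign_reads_once <- function(reads, te_records,
                              group_by = c("group", "subfamily"),
                              mode = c("per_group", "unique_global")) {
  group_by <- match.arg(group_by)
  mode <- match.arg(mode)
  groups <- sort(unique(te_records[[group_by]]))
  counts <- setNames(numeric(length(groups)), groups)
  if (!nrow(reads) || !nrow(te_records)) return(counts)
  hits <- GenomicRanges::findOverlaps(as_granges(reads), as_granges(te_records))
  if (!length(hits)) return(counts)
  pair <- data.frame(
    read_id = reads$read_id[S4Vectors::queryHits(hits)],
    group = te_records[[group_by]][S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  if (mode == "per_group") {
    pair <- unique(pair)
    tab <- table(pair$group)
  } else {
    n_aln <- stats::aggregate(list(n = rep(1, nrow(pair))),
                              by = pair[c("read_id", "group")], FUN = sum)
    n_aln <- n_aln[order(n_aln$read_id, -n_aln$n, n_aln$group), ]
    best <- n_aln[!duplicated(n_aln$read_id), ]
    tab <- table(best$group)
  }
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' Antisense per-length profile against a TE subset
#'
#' Distinct reads per length that are antisense to an insertion of the subset
#' (alignment strand opposite to the insertion strand, overlap of at least
#' one bp), within the size range, and - by default - perfectly mapped (zero
#' mismatches to the genome). Typically run against the full-length intact
#' (FLI) insertions of one group.
#'
#' @param reads alignment data.frame.
#' @param te_subset TE records to profile against (non-empty).
#' @param lib one-row library stats.
#' @param size_range inclusive read lengths (default 24:32).
#' @param perfect_only require `mismatches == 0` (default `TRUE`).
#' @param denominator library total for RPM.
#' @return data.frame `length`, `rpm`.
#' @export
antisense_length_profile <- function(reads, te_subset, lib,
                                     size_range = 24:32, perfect_only = TRUE,
                                     denominator = "total_19_32") {
  if (!nrow(te_subset)) stop("empty TE subset", call. = FALSE)
  reads <- validate_alignments(reads)
  keep <- reads$read_length >= min(size_range) &
    reads$read_length <= max(size_range)
  if (perfect_only) keep <- keep & reads$mismatches == 0
  r <- reads[keep, , drop = FALSE]
  counts <- setNames(numeric(length(size_range)), size_range)
  if (nrow(r)) {
    hits <- GenomicRanges::findOverlaps(as_granges(r), as_granges(te_subset))
    anti <- r$strand[S4Vectors::queryHits(hits)] !=
      te_subset$strand[S4Vectors::subjectHits(hits)]
    ids <- unique(S4Vectors::queryHits(hits)[anti])
    dr <- distinct_reads(r[ids, , drop = FALSE])
    tab <- table(factor(dr$read_length, levels = size_range))
    counts[] <- as.numeric(tab)
  }
  tot <- lib_total(lib, lib$sample_id, denominator)
  data.frame(length = size_range, rpm = unname(counts) * 1e6 / tot)
}

#' TE group expression in RPM across a sample design
#'
#' Once-per-read group counts per sample scaled to RPM and averaged over
#' replicates within genotype (and time point when present).
#'
#' @param reads_by_sample named list of alignment data.frames.
#' @param te_records TE annotation; subset it first for `active_subfamilies`
#'   or `fli_only` scopes (e.g. `te[te$is_fli, ]`).
#' @param libs library stats covering the samples.
#' @param group_by,mode see [assign_reads_once()].
#' @param denominator library total for RPM.
#' @return matrix groups x samples of RPM values.
#' @export
te_group_rpm <- function(reads_by_sample, te_records, libs,
                         group_by = "group", mode = "per_group",
                         denominator = "total_19_32") {
  samples <- names(reads_by_sample)
  mat <- sapply(samples, function(s) {
    cnt <- assign_reads_once(reads_by_sample[[s]], te_records, group_by, mode)
    cnt * 1e6 / lib_total(libs, s, denominator)
  })
  groups <- sort(unique(te_records[[group_by]]))
  matrix(mat, nrow = length(groups), dimnames = list(groups, samples))
}

#' Rank TE groups by knockout/wild-type upregulation
#'
#' Fold change per group is (KO RPM + pseudocount)/(WT RPM + pseudocount),
#' RPM values being replicate means. Output is sorted by fold change
#' descending, ties broken by KO RPM (descending) then group name; the
#' ordering does not depend on input group order. Groups with zero wild-type
#' RPM stay finite through the pseudocount and are flagged `wt_zero`.
#'
#' @param expr_wt,expr_ko named numeric vectors of per-group RPM (same group
#'   universe).
#' @param top_n return the top n groups (default all).
#' @param pseudocount RPM pseudocount (default 0.1).
#' @return data.frame `group`, `wt_rpm`, `ko_rpm`, `fold_change`, `wt_zero`,
#'   ranked.
#' @export
rank_upregulated <- function(expr_wt, expr_ko, top_n = NULL,
                             pseudocount = 0.1) {
  if (!setequal(names(expr_wt), names(expr_ko)))
    stop("WT and KO group universes differ", call. = FALSE)
  g <- sort(names(expr_wt))
  wt <- expr_wt[g]
  ko <- expr_ko[g]
  fc <- (ko + pseudocount) / (wt + pseudocount)
  out <- data.frame(group = g, wt_rpm = unname(wt), ko_rpm = unname(ko),
                    fold_change = unname(fc), wt_zero = unname(wt == 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, -out$ko_rpm, out$group), ]
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Divergence summaries per repeat subfamily
#'
#' Boxplot statistics of percent divergence from consensus (milli_div / 10)
#' per subfamily: median, first and third quartiles (linear-interpolation
#' quantiles) and whiskers at the most extreme data points no further than
#' 1.5 x IQR from the box bounds. Insertion age proxies: young subfamilies
#' show low divergence.
#'
#' @param te_records TE annotation data.frame.
#' @param group_by summarize by `"subfamily"` (default) or `"group"`.
#' @return data.frame `subfamily`, `n_insertions`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high` (percent divergence).
#' @export
divergence_summary <- function(te_records, group_by = "subfamily") {
  if (!nrow(te_records))
    return(data.frame(subfamily = character(), n_insertions = integer(),
                      median = numeric(), q1 = numeric(), q3 = numeric(),
                      whisker_low = numeric(), whisker_high = numeric(),
                      stringsAsFactors = FALSE))
  groups <- split(te_records$milli_div / 10, te_records[[group_by]])
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo <- min(x[x >= q[1] - 1.5 * iqr])
    hi <- max(x[x <= q[3] + 1.5 * iqr])
    data.frame(subfamily = g, n_insertions = length(x), median = q[2],
               q1 = q[1], q3 = q[3], whisker_low = lo, whisker_high = hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
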