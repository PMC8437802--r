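#' Call oocyte piRNA clusters from PIWI immunoprecipitation windows
#'
#' Oocyte clusters are seeded from windowed PIWIL1- and PIWIL3-associated
#' read counts rather than from a knockout contrast: windows of the shared
#' tiling are length-normalized to RPKM and removed when below `rpkm_min` in
#' both IP samples, the surviving windows are merged (adjacent, then
#' superclusters at most `max_gap` apart), and a merged cluster is retained
#' when it reaches `min_ip_rpm` RPM in the PIWIL1 or the PIWIL3 IP (summed
#' over its windows from the unfiltered tables) and the wild-type oocyte
#' libraries average at least `min_wt_rpm` RPM of combined 18-20-nt plus
#' 24-32-nt reads over the interval - the 21-23-nt miRNA/siRNA-rich
#' population is excluded from that quantity. Both 10-RPM filters are
#' inclusive ("a minimum of 10 RPMs").
#'
#' @param piwil1_windows,piwil3_windows single-sample [window_table()]s in
#'   unit `RPM` on the same tiling.
#' @param wt_oocyte_reads named list of wild-type oocyte alignment
#'   data.frames.
#' @param libs library stats covering the wild-type oocyte samples; oocyte
#'   RPM uses `total_18_32` as denominator.
#' @param max_gap supercluster gap (default 2000 bp).
#' @param rpkm_min window prefilter threshold (default 1).
#' @param min_ip_rpm IP retention threshold (default 10 RPM, inclusive).
#' @param min_wt_rpm wild-type combined-size retention threshold (default 10
#'   RPM, inclusive).
#' @return list with `clusters` (retained calls with `piwil1_rpm`,
#'   `piwil3_rpm`, `wt_combined_rpm`) and `candidates` (all merged clusters
#'   with the same columns plus `retained`).
#' @export
call_oocyte_clusters <- function(piwil1_windows, piwil3_windows,
                                 wt_oocyte_reads, libs, max_gap = 2000,
                                 rpkm_min = 1, min_ip_rpm = 10,
                                 min_wt_rpm = 10) {
  stopifnot(inherits(piwil1_windows, "window_table"),
            inherits(piwil3_windows, "window_table"))
  if (piwil1_windows$unit != "RPM" || piwil3_windows$unit != "RPM")
    stop("IP window tables must be in unit RPM", call. = FALSE)
  w1 <- piwil1_windows$windows
  w2 <- piwil3_windows$windows
  if (!identical(w1[, c("chrom", "start", "end")],
                 w2[, c("chrom", "start", "end")]))
    stop("PIWIL1 and PIWIL3 window tables do not share a tiling", call. = FALSE)
  ip <- window_table(w1, cbind(piwil1_windows$values, piwil3_windows$values),
                     "RPM", samples = c("piwil1", "piwil3"))
  ip_rpkm <- to_rpkm(ip)
  kept <- filter_min_rpkm(ip_rpkm, rpkm_min, "any_sample")
  labeled <- kept$windows[, c("chrom", "start", "end")]
  labeled$stage <- if (nrow(labeled)) "oocyte" else character()
  clusters <- merge_superclusters(merge_adjacent(labeled), max_gap)
  if (!nrow(clusters)) {
    empty <- cbind(clusters, piwil1_rpm = numeric(), piwil3_rpm = numeric(),
                   wt_combined_rpm = numeric())
    return(list(clusters = empty, candidates = cbind(empty, retained = logical())))
  }
  ## per-cluster IP RPM summed over all windows of the unfiltered tables
  sum_over <- function(tab) {
    wg <- as_granges(tab$windows)
    hits <- GenomicRanges::findOverlaps(wg, as_granges(clusters))
    out <- numeric(nrow(clusters))
    if (length(hits)) {
      agg <- rowsum(tab$values[S4Vectors::queryHits(hits), 1],
                    group = S4Vectors::subjectHits(hits))
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  clusters$piwil1_rpm <- sum_over(piwil1_windows)
  clusters$piwil3_rpm <- sum_over(piwil3_windows)
  wt_rpm <- sapply(names(wt_oocyte_reads), function(s) {
    r <- wt_oocyte_reads[[s]]
    cnt <- interval_fractional_counts(r, clusters, 18, 20) +
      interval_fractional_counts(r, clusters, 24, 32)
    cnt * 1e6 / lib_total(libs, s, "total_18_32")
  })
  wt_rpm <- matrix(wt_rpm, nrow = nrow(clusters))
  clusters$wt_combined_rpm <- rowMeans(wt_rpm)
  clusters$retained <- (clusters$piwil1_rpm >= min_ip_rpm |
                          clusters$piwil3_rpm >= min_ip_rpm) &
    clusters$wt_combined_rpm >= min_wt_rpm
  retained <- clusters[clusters$retained, , drop = FALSE]
  retained$retained <- NULL
  rownames(retained) <- NULL
  list(clusters = retained, candidates = clusters)
}
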