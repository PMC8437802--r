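#' Window table: per-window values across samples
#'
#' Container for the genome-windowed quantification: an ordered set of
#' windows, a windows x samples numeric matrix in one declared unit
#' (`fractional_count`, `RPM` or `RPKM`), and the per-sample weight that
#' could not be placed because its chromosome had no windows.
#'
#' @param windows data.frame from [tile_genome()] (`chrom`, `start`, `end`,
#'   `effective_length`).
#' @param values numeric matrix, `nrow(windows)` x `length(samples)`.
#' @param unit one of `"fractional_count"`, `"RPM"`, `"RPKM"`.
#' @param samples sample identifiers (defaults to `colnames(values)`).
#' @param unplaced named numeric vector of unplaced weight per sample.
#' @return object of class `window_table`.
#' @export
window_table <- function(windows, values, unit, samples = colnames(values),
                         unplaced = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(windows))
    stop("values matrix does not match windows", call. = FALSE)
  if (ncol(values) != length(samples))
    stop("values matrix does not match samples", call. = FALSE)
  if (nrow(values) && any(values < 0)) stop("negative values", call. = FALSE)
  unit <- match.arg(unit, c("fractional_count", "RPM", "RPKM"))
  colnames(values) <- samples
  if (is.null(unplaced)) unplaced <- setNames(rep(0, length(samples)), samples)
  structure(list(windows = windows, samples = samples, values = values,
                 unit = unit, unplaced = unplaced),
            class = "window_table")
}

#' @export
print.window_table <- function(x, ...) {
  cat(sprintf("window_table: %d windows x %d sample(s), unit %s\n",
              nrow(x$windows), length(x$samples), x$unit))
  invisible(x)
}

#' Tile a genome into fixed windows
#'
#' Consecutive non-overlapping windows of `window_size` bp covering each
#' chromosome; the last window of a chromosome may be shorter. Each window
#' carries its effective length: window length minus overlap with assembly
#' gaps, the length RPKM normalization divides by.
#'
#' @param genome a [genome_model()].
#' @param window_size window size in bp (default 1000).
#' @return data.frame with `chrom`, `start`, `end`, `effective_length`.
#' @export
tile_genome <- function(genome, window_size = 1000) {
  stopifnot(window_size > 0)
  per_chrom <- lapply(seq_len(nrow(genome$chroms)), function(i) {
    len <- genome$chroms$length[i]
    starts <- seq(0, len - 1, by = window_size)
    data.frame(chrom = genome$chroms$name[i], start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, per_chrom) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric())
  w$effective_length <- w$end - w$start
  if (nrow(genome$gaps) && nrow(w)) {
    wg <- as_granges(w)
    gg <- as_granges(genome$gaps)
    hits <- GenomicRanges::findOverlaps(wg, gg)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(wg)[S4Vectors::queryHits(hits)],
        IRanges::ranges(gg)[S4Vectors::subjectHits(hits)]))
      gap_bp <- tapply(ov, S4Vectors::queryHits(hits), sum)
      idx <- as.integer(names(gap_bp))
      w$effective_length[idx] <- w$effective_length[idx] - as.numeric(gap_bp)
    }
  }
  rownames(w) <- NULL
  w
}

## internal: window index (row of `windows`) containing each 0-based bp
## position, NA for chromosomes absent from the tiling. Assumes `windows`
## tile each chromosome contiguously (as produced by tile_genome).
locate_window <- function(chrom, pos, windows) {
  idx <- rep(NA_integer_, length(pos))
  offsets <- split(seq_len(nrow(windows)), windows$chrom)
  for (cn in names(offsets)) {
    rows <- offsets[[cn]]
    sel <- which(chrom == cn)
    if (!length(sel)) next
    k <- findInterval(pos[sel], windows$start[rows])
    k[k < 1 | pos[sel] >= max(windows$end[rows])] <- NA
    idx[sel] <- rows[k]
  }
  idx
}

#' Fractional counts of alignments per window
#'
#' Each alignment of a read whose length lies in `[size_min, size_max]`
#' contributes `1/n_hits` to the window containing its 5' end (left edge on
#' `+`, right edge on `-`). Multimapper weight is fractional against the
#' aligner-reported total hit count, so a read's total contributed weight is
#' (alignments present)/n_hits <= 1. Alignments on chromosomes without
#' windows go to a per-sample unplaced bucket with a warning.
#'
#' @param reads alignment data.frame (see [validate_alignments()]).
#' @param windows data.frame from [tile_genome()].
#' @param size_min,size_max inclusive read-length bounds (defaults 24 and 31,
#'   the piRNA-sized fraction counted into windows).
#' @param sample sample identifier for the single output column.
#' @return single-sample [window_table()] in unit `fractional_count`.
#' @export
fractional_count <- function(reads, windows, size_min = 24, size_max = 31,
                             sample = "sample") {
  stopifnot(size_min <= size_max)
  reads <- validate_alignments(reads)
  keep <- reads$read_length >= size_min & reads$read_length <= size_max
  r <- reads[keep, , drop = FALSE]
  vals <- numeric(nrow(windows))
  unplaced <- 0
  if (nrow(r)) {
    idx <- locate_window(r$chrom, five_prime_pos(r), windows)
    w <- 1 / r$n_hits
    lost <- is.na(idx)
    if (any(lost)) {
      unplaced <- sum(w[lost])
      warning(sprintf("%d alignment(s) on chromosomes without windows (%.4g weight unplaced)",
                      sum(lost), unplaced), call. = FALSE)
    }
    if (any(!lost)) {
      agg <- rowsum(w[!lost], group = idx[!lost])
      vals[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  window_table(windows, matrix(vals, ncol = 1), "fractional_count",
               samples = sample, unplaced = setNames(unplaced, sample))
}

#' Fractional counts for several samples
#'
#' @param reads_by_sample named list of alignment data.frames.
#' @inheritParams fractional_count
#' @return multi-sample [window_table()] in unit `fractional_count`.
#' @export
fractional_count_samples <- function(reads_by_sample, windows, size_min = 24,
                                     size_max = 31) {
  stopifnot(length(reads_by_sample) > 0, !is.null(names(reads_by_sample)))
  tabs <- lapply(names(reads_by_sample), function(s)
    fractional_count(reads_by_sample[[s]], windows, size_min, size_max, s))
  window_table(windows, do.call(cbind, lapply(tabs, function(t) t$values)),
               "fractional_count", samples = names(reads_by_sample),
               unplaced = vapply(tabs, function(t) t$unplaced, 0))
}

## library totals as a lookup, with the divide-by-zero guard shared by all
## normalizations
lib_total <- function(libs, samples, denominator) {
  i <- match(samples, libs$sample_id)
  if (anyNA(i))
    stop("library stats missing for sample(s): ",
         paste(samples[is.na(i)], collapse = ", "), call. = FALSE)
  tot <- libs[[denominator]][i]
  if (any(tot <= 0))
    stop("cannot normalize: zero ", denominator, " for sample ",
         samples[which(tot <= 0)[1]], call. = FALSE)
  tot
}

#' Normalize fractional counts to RPM
#'
#' Reads per million: value x 1e6 / total library reads, where the library
#' total is by default the number of distinct 19-32-nt reads.
#'
#' @param table [window_table()] in unit `fractional_count`.
#' @param libs library stats data.frame (see [library_stats()]).
#' @param denominator `"total_19_32"` (default) or `"total_18_32"`.
#' @return [window_table()] in unit `RPM`.
#' @export
to_rpm <- function(table, libs, denominator = c("total_19_32", "total_18_32")) {
  stopifnot(inherits(table, "window_table"))
  if (table$unit != "fractional_count")
    stop("to_rpm expects unit fractional_count, got ", table$unit, call. = FALSE)
  denominator <- match.arg(denominator)
  tot <- lib_total(libs, table$samples, denominator)
  vals <- sweep(table$values, 2, 1e6 / tot, `*`)
  window_table(table$windows, vals, "RPM", samples = table$samples,
               unplaced = table$unplaced * 1e6 / tot)
}

#' Normalize RPM to RPKM over gap-corrected window length
#'
#' value / (effective_length/1000). Windows with effective length 0 (fully
#' gapped) cannot be length-normalized and are dropped with a message.
#'
#' @param table [window_table()] in unit `RPM`.
#' @return [window_table()] in unit `RPKM`.
#' @export
to_rpkm <- function(table) {
  stopifnot(inherits(table, "window_table"))
  if (table$unit != "RPM")
    stop("to_rpkm expects unit RPM, got ", table$unit, call. = FALSE)
  eff <- table$windows$effective_length
  drop <- eff <= 0
  if (any(drop))
    message(sum(drop), " fully gapped window(s) dropped (effective length 0)")
  keep <- !drop
  vals <- table$values[keep, , drop = FALSE] / (eff[keep] / 1000)
  window_table(table$windows[keep, , drop = FALSE], vals, "RPKM",
               samples = table$samples, unplaced = table$unplaced)
}

#' Remove windows below an RPKM threshold
#'
#' Implements the "windows with RPKM < 1 were removed" prefilter: a window is
#' retained when its RPKM reaches `threshold` in any (default) or all of the
#' deciding samples. Removal is strict `< threshold`, so a window at exactly
#' the threshold survives.
#'
#' @param table [window_table()] in unit `RPKM`.
#' @param threshold RPKM threshold (default 1).
#' @param rule `"any_sample"` or `"all_samples"`.
#' @param samples deciding samples (default: all). The testes pipeline passes
#'   the wild-type samples so that knockout signal loss cannot remove a
#'   window before the fold-change comparison.
#' @return filtered [window_table()], window order preserved.
#' @export
filter_min_rpkm <- function(table, threshold = 1,
                            rule = c("any_sample", "all_samples"),
                            samples = NULL) {
  stopifnot(inherits(table, "window_table"))
  if (table$unit != "RPKM")
    stop("filter_min_rpkm expects unit RPKM, got ", table$unit, call. = FALSE)
  rule <- match.arg(rule)
  samples <- samples %||% table$samples
  j <- match(samples, table$samples)
  if (anyNA(j)) stop("unknown sample(s): ",
                     paste(samples[is.na(j)], collapse = ", "), call. = FALSE)
  v <- table$values[, j, drop = FALSE]
  keep <- if (rule == "any_sample") rowSums(v >= threshold) > 0
          else rowSums(v >= threshold) == length(j)
  window_table(table$windows[keep, , drop = FALSE],
               table$values[keep, , drop = FALSE], "RPKM",
               samples = table$samples, unplaced = table$unplaced)
}
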