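#' Write cluster calls as BED6
#'
#' One line per cluster, 0-based half-open, stage label in the name column
#' and piRNA density (RPM/kb) in the score column clamped to 0-1000 (BED
#' scores are bounded; the unclamped density stays in the TSV output). A
#' header-only file is written for an empty cluster set.
#'
#' @param clusters cluster data.frame with `chrom`, `start`, `end`, `stage`
#'   and optionally `density`.
#' @param path output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  con <- file(path, "w")
  writeLines('track name="piRNA_clusters" description="piRNA cluster calls"',
             con)
  close(con)
  if (!nrow(clusters)) return(invisible(path))
  df <- data.frame(chrom = clusters$chrom, start = clusters$start,
                   end = clusters$end, name = as.character(clusters$stage),
                   score = clusters$density %||% 0,
                   strand = ".", stringsAsFactors = FALSE)
  df$score <- pmin(pmax(round(df$score), 0), 1000)
  write.table(format_coords(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read cluster intervals back from BED6
#' @param path BED path written by [write_clusters_bed()].
#' @return data.frame with `chrom`, `start`, `end`, `stage`, `density`
#'   (score column, clamped on write).
#' @export
read_clusters_bed <- function(path) {
  bed <- read_bed(path)
  if (!nrow(bed))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stage = character(), density = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             stage = bed$name, density = bed$score, stringsAsFactors = FALSE)
}

#' Write one sample of a window table as bedGraph
#'
#' Sorted by chromosome then start; zero-valued windows are omitted (bedGraph
#' is sparse by convention).
#'
#' @param table a [window_table()].
#' @param sample sample identifier (column of the table).
#' @param path output path.
#' @export
write_window_bedgraph <- function(table, sample, path) {
  stopifnot(inherits(table, "window_table"))
  i <- match(sample, table$samples)
  if (is.na(i)) stop("unknown sample: ", sample, call. = FALSE)
  w <- table$windows
  v <- table$values[, i]
  ord <- order(w$chrom, w$start)
  keep <- ord[v[ord] != 0]
  con <- file(path, "w")
  writeLines(sprintf('track type=bedGraph name="%s_%s"', sample, table$unit),
             con)
  close(con)
  df <- data.frame(chrom = w$chrom[keep], start = w$start[keep],
                   end = w$end[keep], value = v[keep])
  write.table(format_coords(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}
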