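#' Genome model: chromosome lengths plus assembly-gap intervals
#'
#' A `genome_model` holds the chromosome names and lengths of an assembly
#' together with the intervals of assembly gaps (N runs). Gap-corrected
#' ("effective") lengths are what RPKM normalization divides by, so gaps are
#' carried with the genome rather than with the windows.
#'
#' All coordinates are 0-based half-open.
#'
#' @param chrom_names character vector of chromosome identifiers (unique).
#' @param chrom_lengths integer vector of chromosome lengths in bp (> 0).
#' @param gaps optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of assembly N runs; merged, sorted and validated.
#' @return An object of class `genome_model`: a list with elements `chroms`
#'   (data.frame `name`, `length`) and `gaps` (data.frame `chrom`, `start`,
#'   `end`).
#' @export
genome_model <- function(chrom_names, chrom_lengths, gaps = NULL) {
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths differ in length", call. = FALSE)
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome name: ",
         chrom_names[duplicated(chrom_names)][1], call. = FALSE)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_lengths) && any(chrom_lengths <= 0))
    stop("all chromosome lengths must be > 0", call. = FALSE)
  gm <- structure(
    list(chroms = data.frame(name = as.character(chrom_names),
                             length = chrom_lengths,
                             stringsAsFactors = FALSE),
         gaps = data.frame(chrom = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)),
    class = "genome_model")
  if (!is.null(gaps) && nrow(gaps)) gm <- set_gaps(gm, gaps)
  gm
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %s bp total, %d gap interval(s)\n",
              nrow(x$chroms), format(sum(x$chroms$length), big.mark = ","),
              nrow(x$gaps)))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chroms$name)
  genome$chroms$length[i]
}

## attach gaps: validate chroms, clip to bounds (with warning), sort + merge
set_gaps <- function(genome, gaps) {
  stopifnot(all(c("chrom", "start", "end") %in% names(gaps)))
  unknown <- setdiff(unique(gaps$chrom), genome$chroms$name)
  if (length(unknown))
    stop("gap on unknown chromosome: ", unknown[1], call. = FALSE)
  check_intervals(gaps$start, gaps$end, "gap")
  len <- chrom_length(genome, gaps$chrom)
  clip_lo <- gaps$start < 0
  clip_hi <- gaps$end > len
  if (any(clip_lo | clip_hi)) {
    warning(sum(clip_lo | clip_hi),
            " gap interval(s) clipped to chromosome bounds", call. = FALSE)
    gaps$start <- pmax(gaps$start, 0)
    gaps$end <- pmin(gaps$end, len)
  }
  gaps <- gaps[gaps$start < gaps$end, , drop = FALSE]
  merged <- lapply(split(gaps, gaps$chrom), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1, end = g$end))
    data.frame(chrom = g$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, unname(merged)) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric())
  ord <- order(match(merged$chrom, genome$chroms$name), merged$start)
  genome$gaps <- merged[ord, , drop = FALSE]
  rownames(genome$gaps) <- NULL
  genome
}

#' Read a chrom.sizes table
#'
#' Two whitespace-separated columns: chromosome name and integer length.
#' Input order is preserved; duplicate names are an error.
#'
#' @param path path to the chrom.sizes file.
#' @return A [genome_model()] with empty gaps.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty chrom.sizes file: ", path, call. = FALSE)
    return(genome_model(character(), numeric()))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2 || is.na(suppressWarnings(as.numeric(p[2]))))
      stop_parse(path, i, "expected '<name> <integer length>'")
  }
  genome_model(vapply(parts, `[[`, "", 1),
               as.numeric(vapply(parts, `[[`, "", 2)))
}

#' Write a chrom.sizes table
#' @param genome a [genome_model()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(genome$chroms, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read assembly-gap intervals (BED3) onto a genome model
#'
#' Gaps are merged if overlapping and clipped to chromosome bounds with a
#' warning; chromosomes absent from `genome` are an error.
#'
#' @param path BED3 file of gap intervals (0-based half-open).
#' @param genome a [genome_model()].
#' @return `genome` with `gaps` attached.
#' @export
read_gaps_bed <- function(path, genome) {
  bed <- read_bed(path)
  set_gaps(genome, bed[, c("chrom", "start", "end")])
}

#' Read a BED file (3 or 6 columns)
#'
#' @param path BED path. Track/browser/comment lines are skipped.
#' @return data.frame with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(vapply(parts, length, 1L))
  if (ncol < 3) stop_parse(path, which(keep)[1], "fewer than 3 BED columns")
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.numeric(vapply(parts, `[[`, "", 2)),
    end = as.numeric(vapply(parts, `[[`, "", 3)),
    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end))
    stop_parse(path, which(is.na(out$start) | is.na(out$end))[1],
               "non-numeric BED coordinate")
  if (any(out$start < 0))
    stop_parse(path, which(out$start < 0)[1], "negative BED coordinate")
  check_intervals(out$start, out$end, "BED interval")
  if (ncol >= 6) {
    out$name <- vapply(parts, `[[`, "", 4)
    out$score <- as.numeric(vapply(parts, `[[`, "", 5))
    out$strand <- vapply(parts, `[[`, "", 6)
  }
  out
}

#' Write intervals as BED (3 or 6 columns)
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(x)))
    cols <- c(cols, "name", "score", "strand")
  df <- x[, cols, drop = FALSE]
  if ("score" %in% names(df)) df$score <- pmin(pmax(round(df$score), 0), 1000)
  write.table(format_coords(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## avoid scientific notation in interval files
format_coords <- function(df) {
  for (col in intersect(c("start", "end"), names(df)))
    df[[col]] <- format(df[[col]], scientific = FALSE, trim = TRUE)
  df
}

## GRanges helpers (0-based half-open in, 1-based closed inside GRanges)
as_granges <- function(df, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if (is.null(strand)) "*" else strand)
}
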