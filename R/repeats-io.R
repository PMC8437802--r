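## RepeatMasker annotation of transposable-element insertions.
##
## A TE record table has one row per insertion: chrom, start, end (0-based
## half-open), strand (+/-), subfamily (RepeatMasker repeat name), group
## (curated family label, e.g. IAP, MYSERV6), class (LTR/LINE/SINE/other),
## milli_div (mismatches to consensus per 1000 bp) and is_fli (full-length
## intact insertion flag).

#' Read a subfamily-to-group mapping table
#'
#' Tab-separated with header: `subfamily`, `group`, `class`, `is_active`.
#' The mapping may be partial; subfamilies absent from it keep their own name
#' as group.
#'
#' @param path mapping file.
#' @return data.frame with the four columns.
#' @export
read_group_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  need <- c("subfamily", "group", "class", "is_active")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("group map lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$is_active <- as.logical(df$is_active)
  df[, need]
}

#' Read a RepeatMasker .out file
#'
#' Standard RepeatMasker layout: three header lines followed by
#' whitespace-separated columns. The 1-based inclusive query coordinates are
#' converted to 0-based half-open, strand `C` to `-`, and the percent
#' divergence column to milli_div (x10). Subfamilies found in `group_map` get
#' its `group`/`class`; others keep `group = subfamily` and class `other`.
#'
#' @param path RepeatMasker .out file.
#' @param group_map optional data.frame from [read_group_map()].
#' @return data.frame of TE records (`is_fli` all `FALSE`; see [mark_fli()]).
#' @export
read_repeatmasker_out <- function(path, group_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  body <- if (length(lines) > 3) lines[-(1:3)] else character()
  body_idx <- which(nzchar(trimws(body)))
  out <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(f) < 14) stop_parse(path, i + 3, "RepeatMasker row with < 14 fields")
    begin <- suppressWarnings(as.numeric(f[6]))
    end <- suppressWarnings(as.numeric(f[7]))
    div <- suppressWarnings(as.numeric(f[2]))
    if (is.na(begin) || is.na(end) || is.na(div))
      stop_parse(path, i + 3, "non-numeric RepeatMasker coordinate/divergence")
    out[[k]] <- data.frame(
      chrom = f[5], start = begin - 1, end = end,
      strand = if (f[9] == "C") "-" else f[9],
      subfamily = f[10], rm_class = f[11],
      milli_div = div * 10, stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), subfamily = character(),
               rm_class = character(), milli_div = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(df)) {
    check_intervals(df$start, df$end, "TE record")
    if (any(!nzchar(df$subfamily))) stop("empty subfamily name", call. = FALSE)
  }
  df$group <- df$subfamily
  df$class <- ifelse(grepl("^LTR", df$rm_class), "LTR",
              ifelse(grepl("^LINE", df$rm_class), "LINE",
              ifelse(grepl("^SINE", df$rm_class), "SINE", "other")))
  if (!is.null(group_map) && nrow(group_map)) {
    i <- match(df$subfamily, group_map$subfamily)
    hit <- !is.na(i)
    df$group[hit] <- group_map$group[i[hit]]
    df$class[hit] <- group_map$class[i[hit]]
  }
  df$is_fli <- FALSE
  df$rm_class <- NULL
  df[, c("chrom", "start", "end", "strand", "subfamily", "group", "class",
         "milli_div", "is_fli")]
}

#' Write TE records as a RepeatMasker .out file
#'
#' Inverse of [read_repeatmasker_out()] for the columns that format encodes:
#' coordinates go back to 1-based inclusive, `-` strand to `C`, milli_div to
#' percent divergence.
#'
#' @param te TE record data.frame.
#' @param path output path.
#' @export
write_repeatmasker_out <- function(te, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query            matching  repeat           position in repeat",
    "score   div. del. ins.  sequence  begin end          (left)    repeat    class/family   begin  end    (left)   ID",
    ""), con)
  if (nrow(te)) {
    rm_class <- ifelse(te$class %in% c("LTR", "LINE", "SINE"),
                       paste0(te$class, "/", te$group), "Unknown")
    writeLines(sprintf(
      " 1000   %4.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
      te$milli_div / 10, te$chrom, as.integer(te$start + 1),
      as.integer(te$end), ifelse(te$strand == "-", "C", "+"),
      te$subfamily, rm_class, as.integer(te$end - te$start),
      seq_len(nrow(te))), con)
  }
  invisible(path)
}

#' Flag full-length intact (FLI) insertions from a BED subset
#'
#' Marks `is_fli = TRUE` for TE records overlapping an interval of the FLI
#' annotation (consumed as given; FLI identification itself is upstream).
#'
#' @param te TE record data.frame.
#' @param fli data.frame with `chrom`, `start`, `end` (e.g. from
#'   [read_bed()]), or a path to a BED file.
#' @return `te` with `is_fli` updated.
#' @export
mark_fli <- function(te, fli) {
  if (is.character(fli)) fli <- read_bed(fli)
  if (!nrow(te) || !nrow(fli)) return(te)
  hits <- GenomicRanges::findOverlaps(as_granges(te), as_granges(fli))
  te$is_fli <- seq_len(nrow(te)) %in% S4Vectors::queryHits(hits)
  te
}
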