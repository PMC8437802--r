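## Aligned small-RNA reads.
##
## One row per genomic alignment of one sequenced read. A multimapping read
## appears once per alignment, all rows sharing read_id and n_hits (the
## aligner-reported total number of genomic hits, which may exceed the rows
## present when the file is a region subset). Columns:
##   read_id, chrom, start, end (0-based half-open), strand (+/-),
##   read_length (nt of the sequenced read), n_hits (>= 1), mismatches,
##   is_primary (logical), clipped5 (logical: the read's 5'-most base is not
##   aligned), sequence (read-orientation nucleotides or NA).

ALN_COLS <- c("read_id", "chrom", "start", "end", "strand", "read_length",
              "n_hits", "mismatches", "is_primary", "clipped5", "sequence")

#' Validate a table of aligned reads
#'
#' Checks the invariants of the internal alignment dialect: `start < end`,
#' `n_hits >= 1`, `mismatches >= 0`, strands in `+`/`-`, and sequence length
#' equal to `read_length` where a sequence is present.
#'
#' @param reads data.frame in the alignment dialect.
#' @return `reads`, invisibly, with columns coerced to canonical types.
#' @export
validate_alignments <- function(reads) {
  missing <- setdiff(ALN_COLS, names(reads))
  if ("sequence" %in% missing) {
    reads$sequence <- NA_character_
    missing <- setdiff(missing, "sequence")
  }
  if (length(missing))
    stop("alignment table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  reads$start <- as.numeric(reads$start)
  reads$end <- as.numeric(reads$end)
  reads$read_length <- as.integer(reads$read_length)
  reads$n_hits <- as.integer(reads$n_hits)
  reads$mismatches <- as.integer(reads$mismatches)
  reads$is_primary <- as.logical(reads$is_primary)
  reads$clipped5 <- as.logical(reads$clipped5)
  if (nrow(reads)) {
    if (any(reads$start < 0)) stop("negative alignment start", call. = FALSE)
    check_intervals(reads$start, reads$end, "alignment")
    if (any(reads$n_hits < 1)) stop("n_hits must be >= 1", call. = FALSE)
    if (any(reads$mismatches < 0)) stop("mismatches must be >= 0", call. = FALSE)
    if (!all(reads$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
    has_seq <- !is.na(reads$sequence)
    if (any(has_seq & nchar(reads$sequence) != reads$read_length))
      stop("sequence length differs from read_length", call. = FALSE)
  }
  invisible(reads[, ALN_COLS])
}

#' Read small-RNA alignments
#'
#' Reads either the package's tab-separated alignment dialect (a header line
#' followed by one row per alignment) or plain-text SAM. For SAM, `n_hits` is
#' taken from the `NH` tag (an error names the first record lacking it),
#' `mismatches` from the `NM` tag (0 when absent), and `clipped5` is derived
#' from the CIGAR strand-aware: a soft/hard clip adjacent to the 5'-most base
#' of the read, which is the left alignment edge on `+` and the right edge
#' on `-`.
#'
#' @param path input file.
#' @param dialect `"tabular"` or `"sam"`.
#' @return data.frame of alignments in file order (see [validate_alignments()]
#'   for columns).
#' @export
read_alignments <- function(path, dialect = c("tabular", "sam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tabular") {
    df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                     stringsAsFactors = FALSE,
                     colClasses = c(sequence = "character"))
    if (!nrow(df)) df$sequence <- character()
    df$sequence[!is.na(df$sequence) & df$sequence == "."] <- NA_character_
    validate_alignments(df)
  } else {
    read_sam(path)
  }
}

#' Write alignments in the tabular dialect
#' @param reads alignment data.frame.
#' @param path output path.
#' @export
write_alignments_tabular <- function(reads, path) {
  reads <- validate_alignments(reads)
  reads$sequence[is.na(reads$sequence)] <- "."
  reads$is_primary <- ifelse(reads$is_primary, "TRUE", "FALSE")
  reads$clipped5 <- ifelse(reads$clipped5, "TRUE", "FALSE")
  write.table(format_coords(reads), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ---- SAM text ----

cigar_ops <- function(cigar) {
  lens <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("bad CIGAR: ", cigar, call. = FALSE)
  list(len = lens, op = ops)
}

read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  n <- length(lines)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop_parse(path, i, "SAM record with < 11 fields")
    flag <- as.integer(f[2])
    pos <- as.numeric(f[4])
    if (is.na(pos) || pos < 1) stop_parse(path, i, "invalid POS")
    strand <- if (bitwAnd(flag, 16L) > 0L) "-" else "+"
    is_primary <- bitwAnd(flag, 256L) == 0L
    cg <- cigar_ops(f[6])
    ref_span <- sum(cg$len[cg$op %in% c("M", "D", "N", "=", "X")])
    read_len <- sum(cg$len[cg$op %in% c("M", "I", "S", "=", "X", "H")])
    first_clip <- length(cg$op) && cg$op[1] %in% c("S", "H")
    last_clip <- length(cg$op) && cg$op[length(cg$op)] %in% c("S", "H")
    clipped5 <- if (strand == "+") first_clip else last_clip
    tags <- f[-(1:11)]
    nh <- sub("^NH:i:", "", grep("^NH:i:", tags, value = TRUE))
    if (!length(nh))
      stop(sprintf("%s: record '%s' lacks the NH hit-count tag", path, f[1]),
           call. = FALSE)
    nm <- sub("^NM:i:", "", grep("^NM:i:", tags, value = TRUE))
    seq <- f[10]
    ## SEQ is reverse-complemented by convention on '-'; restore read
    ## orientation so `sequence` always reads 5'->3' of the sequenced RNA.
    if (seq == "*") seq <- NA_character_
    else if (strand == "-") seq <- revcomp(seq)
    out[[i]] <- data.frame(
      read_id = f[1], chrom = f[3], start = pos - 1, end = pos - 1 + ref_span,
      strand = strand, read_length = read_len,
      n_hits = as.integer(nh[1]),
      mismatches = if (length(nm)) as.integer(nm[1]) else 0L,
      is_primary = is_primary, clipped5 = clipped5, sequence = seq,
      stringsAsFactors = FALSE)
  }
  df <- if (n) do.call(rbind, out) else
    data.frame(read_id = character(), chrom = character(), start = numeric(),
               end = numeric(), strand = character(), read_length = integer(),
               n_hits = integer(), mismatches = integer(),
               is_primary = logical(), clipped5 = logical(),
               sequence = character(), stringsAsFactors = FALSE)
  validate_alignments(df)
}

revcomp <- function(x) {
  chartr("ACGTUacgtu", "TGCAATGCAA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                "", USE.NAMES = FALSE))
}

#' Write alignments as plain-text SAM
#'
#' Emits a minimal header (`@HD`, `@SQ`) and one record per alignment with
#' `NH` and `NM` tags. Sequences of fully aligned reads are written in SAM
#' (reference) orientation; clipped reads are written with a soft clip at the
#' unaligned 5' base(s) so that CIGAR round-trips `clipped5`.
#'
#' @param reads alignment data.frame.
#' @param genome a [genome_model()] providing `@SQ` lines.
#' @param path output path.
#' @export
write_alignments_sam <- function(reads, genome, path) {
  reads <- validate_alignments(reads)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", genome$chroms$name,
                     as.integer(genome$chroms$length)), con)
  if (!nrow(reads)) return(invisible(path))
  aligned <- reads$end - reads$start
  clip <- pmax(reads$read_length - aligned, 0)
  cigar <- ifelse(clip == 0, paste0(aligned, "M"),
                  ifelse((reads$strand == "+") == reads$clipped5,
                         paste0(clip, "S", aligned, "M"),
                         paste0(aligned, "M", clip, "S")))
  flag <- ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$is_primary, 0L, 256L)
  seq <- reads$sequence
  seq[is.na(seq)] <- "*"
  flip <- reads$strand == "-" & seq != "*"
  seq[flip] <- revcomp(seq[flip])
  writeLines(paste(reads$read_id, flag, reads$chrom,
                   format(reads$start + 1, scientific = FALSE, trim = TRUE),
                   255L, cigar, "*", 0L, 0L, seq, "*",
                   paste0("NH:i:", reads$n_hits),
                   paste0("NM:i:", reads$mismatches), sep = "\t"), con)
  invisible(path)
}

## 5' genomic position of each alignment (0-based bp): left edge on '+',
## right edge on '-'.
five_prime_pos <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1)
}
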