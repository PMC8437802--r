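## Read-level piRNA statistics: length distributions, size classes, miRNA
## scaling and 1U/10A nucleotide bias. These operate on distinct reads
## (deduplicated by read_id), never on alignment multiplicity: a read's
## length, sequence and annotation membership are read properties.

## one row per distinct read, taking read-level fields from the first
## (preferring primary) alignment
distinct_reads <- function(reads) {
  if (!nrow(reads)) return(reads)
  ord <- order(!reads$is_primary)
  r <- reads[ord, , drop = FALSE]
  r[!duplicated(r$read_id), , drop = FALSE]
}

#' Library statistics for normalization
#'
#' Counts distinct reads (each read once, regardless of its number of
#' alignments) with lengths 19-32 and 18-32 nt, and the number of reads
#' assigned as miRNA-derived: reads with at least one alignment overlapping
#' the miRNA annotation when one is given, otherwise the 21-23-nt size class
#' as a proxy.
#'
#' @param reads alignment data.frame.
#' @param sample_id sample identifier.
#' @param mirna optional miRNA annotation: data.frame with `chrom`, `start`,
#'   `end` or a BED path.
#' @return one-row data.frame: `sample_id`, `total_19_32`, `total_18_32`,
#'   `mirna_count`.
#' @export
library_stats <- function(reads, sample_id, mirna = NULL) {
  reads <- validate_alignments(reads)
  dr <- distinct_reads(reads)
  if (is.null(mirna)) {
    mirna_count <- sum(dr$read_length >= 21 & dr$read_length <= 23)
  } else {
    if (is.character(mirna)) mirna <- read_bed(mirna)
    if (nrow(mirna) && nrow(reads)) {
      hits <- GenomicRanges::findOverlaps(as_granges(reads), as_granges(mirna))
      mirna_count <- length(unique(
        reads$read_id[S4Vectors::queryHits(hits)]))
    } else mirna_count <- 0L
  }
  data.frame(sample_id = sample_id,
             total_19_32 = sum(dr$read_length >= 19 & dr$read_length <= 32),
             total_18_32 = sum(dr$read_length >= 18 & dr$read_length <= 32),
             mirna_count = as.integer(mirna_count),
             stringsAsFactors = FALSE)
}

#' Read-length distribution in RPM
#'
#' Distinct reads per length (a read with five alignments still counts once)
#' scaled to reads per million of the chosen library total.
#'
#' @param reads alignment data.frame.
#' @param lib one-row library stats for this sample.
#' @param length_range lengths reported (default 18:32).
#' @param denominator `"total_19_32"` (default) or `"total_18_32"`.
#' @return data.frame `length`, `rpm`, plus attributes `sample_id` and
#'   `scaling_factor` (1 until rescaled, see [mirna_scaling_factor()]).
#' @export
length_profile <- function(reads, lib, length_range = 18:32,
                           denominator = c("total_19_32", "total_18_32")) {
  denominator <- match.arg(denominator)
  tot <- lib[[denominator]]
  if (is.null(tot) || length(tot) != 1 || tot <= 0)
    stop("library total ", denominator, " must be a single positive count",
         call. = FALSE)
  dr <- distinct_reads(validate_alignments(reads))
  counts <- vapply(length_range, function(L) sum(dr$read_length == L), 0)
  out <- data.frame(length = length_range, rpm = counts * 1e6 / tot)
  attr(out, "sample_id") <- lib$sample_id
  attr(out, "scaling_factor") <- 1
  out
}

SIZE_CLASSES <- list("18-20" = 18:20, "21-23" = 21:23,
                     "24-27" = 24:27, "28-31" = 28:31)

#' Sum a length profile into piRNA size classes
#'
#' Bins 18-20 (putative PIWIL3-bound piRNAs), 21-23 (Dicer products), 24-27
#' and 28-31 nt (smaller and longer piRNAs); bounds inclusive.
#'
#' @param profile data.frame from [length_profile()].
#' @return data.frame `size_class`, `rpm`.
#' @export
size_class_summary <- function(profile) {
  if (!all(18:31 %in% profile$length))
    stop("profile must cover lengths 18-31", call. = FALSE)
  rpm <- vapply(SIZE_CLASSES, function(ls)
    sum(profile$rpm[profile$length %in% ls]), 0)
  data.frame(size_class = names(SIZE_CLASSES), rpm = unname(rpm),
             stringsAsFactors = FALSE)
}

#' miRNA-based scaling factor for a knockout library
#'
#' When piRNAs collapse in the knockout, per-million normalization silently
#' inflates everything else; scaling by the (genotype-independent) miRNA
#' population restores comparability. The factor is the mean wild-type miRNA
#' RPM (each library against its own total) divided by the knockout miRNA
#' RPM; multiplying knockout RPM values by it equalizes miRNA RPM across
#' genotypes.
#'
#' @param ko_lib one-row library stats of the knockout library.
#' @param wt_libs library stats data.frame of one or more wild-type
#'   libraries.
#' @param denominator library total against which miRNA RPM is computed.
#' @return scaling factor (positive scalar).
#' @export
mirna_scaling_factor <- function(ko_lib, wt_libs,
                                 denominator = c("total_19_32", "total_18_32")) {
  denominator <- match.arg(denominator)
  if (any(c(ko_lib$mirna_count, wt_libs$mirna_count) <= 0))
    stop("zero miRNA count; cannot compute scaling factor", call. = FALSE)
  wt_rpm <- wt_libs$mirna_count * 1e6 / wt_libs[[denominator]]
  ko_rpm <- ko_lib$mirna_count * 1e6 / ko_lib[[denominator]]
  mean(wt_rpm) / ko_rpm
}

#' Select logo-eligible piRNA sequences
#'
#' Reads feeding the nucleotide-bias matrix, per the four-way predicate:
#' primary alignments only, 5'-most base aligned (no 5' clip), read length
#' within `length_range` (default 25-31 nt) and 5' end inside a piRNA
#' cluster. Sequences are returned 5'->3' in read orientation with T
#' normalized to U.
#'
#' @param reads alignment data.frame carrying sequences.
#' @param clusters data.frame with `chrom`, `start`, `end` cluster intervals.
#' @param length_range inclusive read-length range (default 25:31).
#' @return character vector of RNA sequences.
#' @export
select_logo_reads <- function(reads, clusters, length_range = 25:31) {
  reads <- validate_alignments(reads)
  keep <- reads$is_primary & !reads$clipped5 &
    reads$read_length >= min(length_range) &
    reads$read_length <= max(length_range)
  r <- reads[keep, , drop = FALSE]
  if (!nrow(r) || !nrow(clusters)) return(character())
  p5 <- five_prime_pos(r)
  rg <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(p5 + 1, width = 1))
  inside <- IRanges::overlapsAny(rg, as_granges(clusters))
  r <- r[inside, , drop = FALSE]
  if (any(is.na(r$sequence)))
    stop("logo-eligible read without sequence: ",
         r$read_id[is.na(r$sequence)][1], call. = FALSE)
  chartr("Tt", "Uu", toupper(r$sequence))
}

#' Position frequency matrix of a sequence set
#'
#' Relative base frequencies per 5'->3' position (position 1 = first
#' nucleotide). Variable lengths are allowed: each position's denominator is
#' the number of sequences long enough to cover it; N bases are excluded
#' from the denominator at their position.
#'
#' @param sequences character vector over the alphabet A/C/G/U/N (T accepted
#'   and read as U).
#' @return matrix of positions x bases (A, C, G, U) with attribute `n_reads`;
#'   rows sum to 1 where any base was observed.
#' @export
position_frequencies <- function(sequences) {
  if (!length(sequences)) stop("no sequences", call. = FALSE)
  sequences <- chartr("Tt", "Uu", toupper(sequences))
  L <- max(nchar(sequences))
  bases <- c("A", "C", "G", "U")
  counts <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, bases))
  split_mat <- strsplit(sequences, "")
  for (s in split_mat) {
    idx <- match(s, bases)
    ok <- !is.na(idx)
    pos <- which(ok)
    if (length(pos))
      counts[cbind(pos, idx[ok])] <- counts[cbind(pos, idx[ok])] + 1
  }
  denom <- rowSums(counts)
  freq <- counts / ifelse(denom > 0, denom, 1)
  attr(freq, "n_reads") <- length(sequences)
  freq
}

#' 1U/10A bias statistics from a position frequency matrix
#'
#' The two diagnostic piRNA biases: frequency of uridine at position 1 (the
#' 5' end, a primary-processing signature) and of adenosine at position 10
#' (the ping-pong signature).
#'
#' @param pfm matrix from [position_frequencies()].
#' @return list with `u1_fraction` and `a10_fraction` (`NA` if the matrix is
#'   shorter than 10 positions).
#' @export
bias_stats <- function(pfm) {
  list(u1_fraction = unname(pfm[1, "U"]),
       a10_fraction = if (nrow(pfm) >= 10) unname(pfm[10, "A"]) else NA_real_)
}
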