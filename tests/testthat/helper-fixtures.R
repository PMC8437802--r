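## Shared fixtures: tiny in-code constructors for alignments, genomes and
## designs. Everything is generated programmatically; no stored data.

aln <- function(read_id, start, end = NULL, chrom = "chr1", strand = "+",
                read_length = 28, n_hits = 1L, mismatches = 0L,
                is_primary = TRUE, clipped5 = FALSE, sequence = NA_character_) {
  if (!length(read_id)) return(empty_aln())
  if (is.null(end)) end <- start + read_length
  data.frame(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, read_length = read_length, n_hits = n_hits,
             mismatches = mismatches, is_primary = is_primary,
             clipped5 = clipped5, sequence = sequence,
             stringsAsFactors = FALSE)
}

empty_aln <- function() {
  data.frame(read_id = character(), chrom = character(), start = numeric(),
             end = numeric(), strand = character(), read_length = integer(),
             n_hits = integer(), mismatches = integer(),
             is_primary = logical(), clipped5 = logical(),
             sequence = character(), stringsAsFactors = FALSE)
}

## six-sample WT/KO x three-time-point design, one replicate each
design6 <- function() {
  data.frame(
    sample_id = c("wt9", "wt13", "wt21", "ko9", "ko13", "ko21"),
    genotype = rep(c("WT", "KO"), each = 3),
    timepoint = rep(c("9dpp", "13dpp", "21dpp"), 2),
    role = "testes", stringsAsFactors = FALSE)
}

libs_for <- function(sample_ids, total = 1e6) {
  data.frame(sample_id = sample_ids, total_19_32 = total,
             total_18_32 = total, mirna_count = 1L,
             stringsAsFactors = FALSE)
}

## n unique-mapper reads of one length with 5' ends uniform in [lo, hi)
reads_in <- function(n, lo, hi, prefix = "r", read_length = 28,
                     chrom = "chr1") {
  if (n == 0) return(empty_aln())
  p5 <- lo + (seq_len(n) - 1) %% (hi - lo)
  aln(sprintf("%s%04d", prefix, seq_len(n)), start = p5,
      end = p5 + read_length, chrom = chrom, read_length = read_length)
}

## deterministic scaled-down testes config for unit tests (shipped defaults
## stay untouched)
small_testes_config <- function(seed = 5, depth = 3e4) {
  sim_config_testes(seed = seed, depth = depth)
}
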