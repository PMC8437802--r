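Package: pirnascape
Title: Windowed piRNA Cluster Discovery and Retrotransposon Quantification
    for Knockout/Wild-Type Small-RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers piRNA clusters from genome-windowed small-RNA-seq
    alignments by comparing knockout and wild-type libraries across
    developmental time points (pre-pachytene versus pachytene testes stages,
    plus an immunoprecipitation-seeded oocyte variant), using fractional
    counting of multimapping reads, RPM/RPKM normalization over gap-corrected
    window lengths, log2 fold-change classification, supercluster merging and
    piRNA-density filtering. Also provides piRNA read-level statistics (length
    profiles and size classes, miRNA-based cross-library scaling, 1U/10A
    nucleotide-bias matrices), retrotransposon-centric quantification
    (once-per-read group counting, antisense perfect-match length profiles
    against full-length intact insertions, knockout/wild-type ranking,
    RepeatMasker divergence summaries) and a fully deterministic synthetic
    alignment generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
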