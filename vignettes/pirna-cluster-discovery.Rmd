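---
title: "Windowed piRNA cluster discovery from knockout/wild-type small-RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed piRNA cluster discovery from knockout/wild-type small-RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnascape)
```

## The problem

PIWI-interacting RNAs (piRNAs) are 19–32-nt germline small RNAs that arise
from discrete genomic loci — piRNA clusters — and silence retrotransposons.
In species without curated cluster annotation, clusters can be discovered
functionally: when piRNA biogenesis is ablated (here, loss of the RNA
helicase MOV10L1), genuine cluster-derived reads collapse in the knockout
while other small-RNA populations (miRNAs, degradation fragments) do not.
`pirnascape` implements that comparative discovery strategy for a
knockout/wild-type (KO/WT) developmental time course of testes small-RNA-seq
libraries, an immunoprecipitation-seeded variant for oocytes, and the
surrounding quantification statistics: read-length profiles and size
classes, miRNA-based cross-library rescaling, 1U/10A nucleotide-bias
matrices, and retrotransposon-centric summaries (once-per-read group counts,
antisense perfect-match profiles against full-length intact (FLI)
insertions, divergence landscapes).

Everything is exercised end-to-end on synthetic alignments with planted
ground truth, so the pipeline is testable at desk scale without any
sequencing download.

## The testes procedure

For each sample the genome is tiled into 1-kb windows and alignments of
24–31-nt reads are counted **fractionally**: each alignment of a read
contributes $1/n_\mathrm{hits}$ to the window containing its 5′ end, where
$n_\mathrm{hits}$ is the aligner-reported total hit count of that read.
Counts become RPM by normalizing to the number of distinct 19–32-nt reads in
millions, and RPKM by dividing by the window length in kb *excluding
assembly gaps* (N runs). Windows with RPKM < 1 are removed; the removal is
strict, so a window at exactly 1 survives.

Per window and time point, replicate RPKMs are averaged within genotype and
the KO/WT contrast is

$$\mathrm{lfc} = \log_2\frac{\overline{\mathrm{RPKM}}_{KO} + p}
                            {\overline{\mathrm{RPKM}}_{WT} + p},
  \qquad p = 0.01,$$

with strict classification rules:

* **pre-pachytene**: lfc < −2 at both 9 and 13 days postpartum (d.p.p.);
* **pachytene**: lfc < −2 at 21 d.p.p. *and* lfc > −2 at 13 d.p.p.;
* a window exactly at −2 satisfies neither rule.

Immediately adjacent same-label windows merge into clusters; clusters at
most 2 kb apart (inclusive) merge into superclusters, never across stage
labels. Final RPKMs are then *recomputed* over each merged interval, and a
cluster is retained when its piRNA density — the replicate-averaged
wild-type RPM of the stage-defining time points (mean of 9 and 13 d.p.p.
for pre-pachytene, 21 d.p.p. for pachytene) per gap-corrected kilobase —
strictly exceeds 10 RPM/kb (pre-pachytene) or 100 RPM/kb (pachytene).

```{r testes, eval = FALSE}
cfg <- sim_config_testes(seed = 1)
sim <- simulate_dataset(cfg)
res <- run_testes_pipeline(sim)
res$clusters
```

### Choices made where the procedure was open

* **Pseudocount 0.01 RPKM on both sides.** Knockout windows routinely have
  zero reads; the fold change must stay finite yet classify as "lower than
  −2". For a window expressed at $x$ RPKM on the smaller side, the
  pseudocount can move the fold change by at most $\log_2((x+p)/x)$, which
  at the RPKM ≥ 1 prefilter bound is ≤ 0.015 — far from the −2 boundary.
  This bound is asserted as a property test.
* **RPKM < 1 prefilter evaluated on wild-type samples, any-sample rule.**
  The filter runs before the KO/WT comparison; evaluating it on knockout
  samples would delete precisely the windows whose knockout collapse the
  classifier needs to see. Both the sample set and the any/all rule are
  arguments of `filter_min_rpkm()`.
* **Pachytene threshold read as 100 RPM per kilobase.** The defining
  sentence elides the unit after "10 RPM per kilobase"; per-kilobase is the
  parallel reading. `filter_density(pachytene_per_kb = FALSE)` provides the
  alternative "100 RPM total per cluster" reading.
* **Supercluster merging never joins different stages**, and the merged
  interval spans first start to last end; the operation is idempotent and
  input-order-invariant (tested).
* **Manual curation is a declarative file.** The original analysis included
  a manual curation pass that cannot be reproduced mechanically; its
  stand-in is an include/exclude interval table applied by
  `finalize_clusters()`, so every run of the pipeline is deterministic.
* **Density uses the gap-corrected interval length**, consistent with the
  RPKM it accompanies.

## The oocyte variant

Oocytes lack a usable KO/WT contrast for seeding (the knockout loss is
massive but incomplete), so candidate windows come from PIWIL1- and
PIWIL3-IP libraries instead: windows of the shared tiling pass when either
IP reaches RPKM ≥ 1, merge exactly as above, and a merged cluster is
retained when (i) it reaches **10 RPM** (inclusive) in the PIWIL1 *or*
PIWIL3 IP and (ii) the wild-type oocyte libraries average **10 RPM**
(inclusive) of combined 18–20-nt plus 24–32-nt reads over the interval —
the 21–23-nt miRNA/siRNA-rich population is excluded, which is what rejects
miRNA loci that co-purify in the IPs. Oocyte libraries are normalized to
their total 18–32-nt reads (the oocyte libraries are normalized to total
reads; within the simulation all reads lie in 18–32 nt).

## Read-level statistics

* **Length profiles** count *distinct reads* per length (a read with five
  alignments counts once) in RPM; size classes 18–20 / 21–23 / 24–27 /
  28–31 nt separate putative PIWIL3-bound piRNAs, Dicer products, and
  smaller/longer piRNAs.
* **miRNA rescaling.** When piRNAs collapse, per-million normalization
  inflates everything that remains. The scaling factor is the mean
  wild-type miRNA RPM over the knockout miRNA RPM; applying it to knockout
  RPM values equalizes miRNA abundance across genotypes exactly (an
  algebraic identity, asserted to 1e-9). The miRNA set is taken from a BED
  annotation when provided, else the 21–23-nt size class serves as proxy.
* **1U/10A bias.** Logo-eligible reads are primary alignments with an
  aligned first nucleotide (no 5′ clip), 25–31 nt long, with their 5′ end
  inside a cluster. Position frequencies are computed 5′→3′ (position 1 =
  first nucleotide), pooled over all clusters; a per-stage split is a
  one-line subset of the cluster table. `bias_stats()` reports the U
  fraction at position 1 and the A fraction at position 10, the primary
  processing and ping-pong signatures.

## Retrotransposon quantification

* **Once-per-read group counts.** A read contributes exactly 1 to each TE
  group that any of its alignments overlaps (≥ 1 bp), however many
  insertions of that group it hits. Whether a read may count in *several
  different* groups is genuinely ambiguous; the default allows it, and
  `mode = "unique_global"` assigns the read to its best single group
  (most alignments, ties lexicographic).
* **Antisense FLI profiles** keep perfectly mapped reads (zero mismatches
  to the genome — mismatches to an insertion consensus are not computable
  from alignments alone), antisense to an insertion of the subset, 24–32
  nt, counted as distinct reads per length.
* **Divergence summaries** report boxplot statistics of percent divergence
  per subfamily: linear-interpolation quartiles (`quantile(type = 7)`, the
  default of mainstream statistical environments, so an independent oracle
  matches exactly) and whiskers at the most extreme points within 1.5 × IQR
  of the box.
* **Upregulation ranking** orders groups by (KO RPM + 0.1)/(WT RPM + 0.1),
  ties broken by KO RPM then name, making the order input-independent and
  zero-WT groups finite (flagged `wt_zero`).

## What the generator emulates — and what it does not

`sim_config_testes()` is the shipped study condition: two 1-Mb chromosomes,
1-kb windows, 2% assembly gaps, six planted clusters — three pre-pachytene
(40/60/80 RPM/kb), two pachytene (200/300 RPM/kb) and one pre-pachytene
*decoy* at 3 RPM/kb that classifies correctly but must be rejected by the
density filter — all with knockout retention 0; 1U/10A probabilities
0.8/0.5; three LTR subfamilies (MYSERV6, MYSERV, IAP with a 40% FLI subset)
at knockout fold increases 20× / 3.3× / 2×, the fold magnitudes reported
for these groups in hamster testes; twelve libraries (WT/KO × 9/13/21
d.p.p. × 2 replicates) at 200,000 reads each. Multimappers (15%, up to 4
hits) keep all alignments within their source element, emulating the
repeat-rich character of clusters while keeping the planted truth exact.

Non-piRNA read mass is placed at *dense annotated loci* — miRNA loci at
21–23 nt and "background" expressed loci shared by both genotypes — rather
than sprinkled uniformly over the genome. This is the noiseless end-to-end
condition: all sources of signal are planted, so recovered clusters can be
compared to the truth by set equality. A sparse uniform background would
occasionally produce single-window loci with wild-type reads and zero
knockout reads purely by sampling — which the classification rules would
*correctly* call clusters, because at that depth they are statistically
indistinguishable from real ones. The RPKM < 1 prefilter is instead
exercised by the vast majority of windows (those without any planted
element) and by dedicated unit tests with sparse backgrounds. Planted
elements are kept ≥ 4.5 kb apart so that 1-kb window quantization can never
let the 2-kb supercluster step bridge two distinct elements.

What the generator does **not** emulate, and what green tests therefore do
not show about real data: sequencing error and adapter artefacts; mapping
ambiguity beyond the `n_hits` abstraction (no sequence-level alignment is
performed); expression gradients within clusters and partial knockout
retention in testes; genomic copies of miRNAs inside clusters; and any
between-replicate biological variance beyond Poisson sampling. Conclusions
about threshold robustness on real libraries need the real data.

## Numerical and size choices

All computation is exact double arithmetic; conservation properties
(fractional-count totals, length-profile totals) are asserted to 1e-9.
Degenerate inputs have defined behaviour: fully gapped windows and clusters
are dropped with a message/warning, empty inputs yield empty outputs of the
right shape, zero library totals and zero miRNA counts are errors.
Coordinates are 0-based half-open internally; conversions happen only at
format boundaries (BED, SAM, RepeatMasker .out), and each writer/reader
pair round-trips.

Problem sizes were chosen so the whole validation runs comfortably on one
CPU: the shipped testes condition (12 × 200k reads over 2 Mb) takes well
under two minutes end-to-end, the oracle-equivalence suite uses 50 random
instances of ≤ 100 windows × ≤ 200 reads against an independently coded
brute-force enumeration, and the bias-recovery check draws ≥ 10,000
logo-eligible reads from a single deep cluster. The per-library RNG stream
is seeded from (config seed, sample index), so any library can be
regenerated in isolation and whole-dataset runs are byte-identical under a
fixed seed.

## Known limitations

* The multihit cap is the upstream aligner's business: `n_hits` is trusted
  from input, never recomputed, because a region-subset file cannot know a
  read's genome-wide hit count.
* SAM support is plain-text single-end records with NH/NM tags (the
  dialect the tests and fixtures use); coordinate-sorted BAM workflows
  should convert with `samtools view` first.
* The oocyte IP windows use all 18–32-nt IP reads; if an IP library
  contains abundant longer RNAs the size range argument of
  `fractional_count()` is the knob to narrow.
* "Active subfamilies" are consumed as an annotation flag, not inferred
  from divergence/abundance cutoffs.
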