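---
title: "Methods: isoform reconstruction and characterization from full-length reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform reconstruction and characterization from full-length reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscribe)
```

# The problem

A full-length cDNA read carries the complete exon-intron structure of one
transcript molecule, so a collection of genome-aligned full-length reads
can be turned directly into an isoform-level annotation: reads with the
same intron chain are evidence for the same isoform, and reads whose
chains are 3'-anchored fragments of a longer chain are most plausibly 5'
degradation products of that longer isoform. `isoscribe` implements this
construction, plus the downstream characterization a transcriptome survey
needs: novelty classification against existing reference annotations,
expression quantification, tissue-specificity scoring, local
alternative-splicing event enumeration, and a positional null test for
intergenic transcripts.

All internal coordinates are 0-based half-open on a named chromosome;
GTF readers and writers convert at the boundary. This single convention
is deliberate: mixing conventions is the classic source of off-by-one
drift in interval pipelines.

# Transcript-model construction

Construction proceeds in four stages, each controlled by a
`tolerance_set()`:

1. **Clustering** (`cluster_alignments`). Reads are sorted canonically by
   (chrom, strand, intron count, first boundary) and assigned greedily to
   the first cluster whose *seed* read has every intron boundary within
   `cluster_internal` = 20 bp. Single-exon reads instead match both
   terminal ends within `cluster_terminal` = 60 bp. Terminal tolerance is
   *not* enforced for multi-exon reads: a 5'-degraded read must still
   co-cluster collapse-ward, and 5' variability is resolved later.
   Clusters need `min_cluster_size` = 3 alignments to be emitted.
   Greedy first-fit against the seed is our linkage choice; it is
   deterministic under the canonical sort, which makes the whole stage
   order-invariant.
2. **Consensus** (`consensus_model`). Each boundary of the model is the
   member-wise median, taking the lower value on even counts. The tie
   rule is arbitrary but fixed, again for reproducibility. A consensus
   that collapses an exon or intron to zero length rejects the cluster
   with a warning; this can only happen for clusters mixing structurally
   incompatible reads at the tolerance edge.
3. **Locus assignment** (`assign_loci`). Models on the same chrom and
   strand whose strand-aware 3' ends lie within `collapse_3prime` =
   100 bp are connected; connected components are loci. The procedure's
   source only says loci are formed "based on 3' ends"; we reuse the
   100 bp 3' tolerance as the grouping distance, which we flag as a
   choice rather than a documented constant.
4. **Collapse** (`collapse_models`). Within a locus, model A is absorbed
   into model B when A's intron chain is a contiguous 3'-terminal
   subsequence of B's (each boundary within `collapse_internal` = 5 bp),
   the 3' ends agree within 100 bp, and A's 5' end is within
   `collapse_5prime` = 5,000 bp of its projected position on B. The
   5,000 bp window is what makes the stage degradation-aware: a molecule
   can lose kilobases of 5' sequence and still be attributed to its
   source isoform. Fragments are visited fewest-introns-first so each
   meets its longest superset first; the survivor among several
   candidates has the most introns, then the higher support, the longer
   span, the smaller start. The loop runs to a fixed point, so the
   output provably contains no absorbable pair (a property the test
   suite checks against an exhaustive oracle).

A consequence worth stating plainly: **an isoform whose chain is a
boundary-compatible 3'-terminal subsequence of a sibling's chain is
indistinguishable from that sibling's degradation products.** No
parameter setting can recover such a pair separately. The synthetic-data
generator therefore never creates one (see below).

# Novelty classification

`assign_class_code()` re-implements the one-character structural codes
this kind of comparison tool emits, because the category mapping depends
on their semantics and those semantics are nowhere restated in a single
place. The precedence order is fixed and documented on the help page:
`=`, `c`, `k`, `m`, `n`, `j`, `e`, `o`, `i`, `y`, `x`, `p`, `s`, `u`,
i.e. specific codes strictly before the same-strand catch-all `o`, then
positional codes. `=` requires exact intron boundaries (0 bp tolerance)
with free terminal ends — degradation tolerance belongs to collapse, not
to matching. The run-on window for `p` is 2,000 bp downstream on the
same strand.

Categories follow the published mapping: `=` against either annotation
means known isoform; else any of `c/k/j/m/n/o` means novel isoform; else
any of `i/u/y/x` means novel locus; a model seen only as `e/s/p` is a
potential artifact. Single-exon models are filtered afterwards: retained
only with same-strand exon overlap of a protein-coding gene, or with
support of at least 100 alignments.

For accuracy grids (`accuracy_metrics`), sensitivity and precision are
computed at base, exon, intron, transcript and locus level. Exon
matching treats transcript-terminal boundaries as free, introns and
transcripts match exactly, and missed/novel feature counts use
no-overlap semantics (a reference exon is "missed" only when nothing
overlaps it), which is how the original comparison tool counts them.

# Quantification

Reads are assigned to models by 3'-anchored compatibility: the read's
intron chain must be a contiguous 3'-terminal subsequence of the model's
within the 20 bp cluster tolerance, with the read inside the model span.
3' anchoring reflects the asymmetry of the data — 3' ends of oligo-dT
primed full-length reads are reliable, 5' ends are not. Ambiguous reads
(several models share a 3' suffix) are split by a standard EM:
initialize uniform, E-step splits each read across its compatible set
proportionally to current abundances, M-step renormalizes, iterate to
`rel_tol` = 1e-6 or 100 iterations. Estimated counts always sum to the
assigned read count, and TPM is `proportion * 1e6` with **no transcript
length term**: each full-length read represents one molecule, so length
normalization would bias the estimates, not correct them.

# Tissue specificity

For each transcript the tissue-specificity index is
`TSI = max_i(x_i) / sum_i(x_i)` over per-tissue mean TPM `x_i`, with the
mean (not median — the procedure specifies the average) over included
replicates. TSI is 1/n for uniform expression and 1 for single-tissue
expression, and is invariant to rescaling. Boundaries are taken
literally from the interval notation: tissue-specific when TSI >= 0.8,
broad when TSI < 0.5, intermediate in between. Exclusion rules mirror
the source procedure: user-specified samples are dropped, tissues with
fewer than two remaining replicates are dropped, and transcripts
expressed in exactly one sample are excluded from TSI entirely. No
additional expression floor is applied — the procedure does not state
one, so we do not invent one; the stratified summary by mean-TPM band
(<1, 1–10, >=10) makes the dependence on expression level visible
instead. Unique-TSS attribution widens each tissue-specific transcript's
strand-aware TSS by ±50 bp and calls it unique when no other predicted
transcript's widened TSS overlaps it on the same strand (two TSS are
therefore non-unique up to 100 bp apart, unique from 101 bp).

# Splicing events and positional statistics

`enumerate_events()` generates the seven local event types (SE, MX, RI,
A5, A3, AF, AL) from pairwise comparison of each locus's transcripts,
with the usual local-event definitions; A5/A3 additionally require the
variable stretch between the two alternative splice sites to be fully
exonic in the transcript carrying the shorter intron, and AF/AL require
distinct, non-overlapping first (last) exons with distinct inner splice
sites joining the same downstream (upstream) boundary — without the
non-overlap requirement every A5 event would double-report as AF.
Events are deduplicated on their coordinate tuple per locus and type.

For intergenic models (`code u`), `intergenic_proximity_test()` compares
nearest-gene distances of the observed intervals against the same
intervals re-placed uniformly at random on the genome with gene regions
excluded (rejection sampling, 10,000 tries per interval, seeded).
Placement is genome-wide with chromosome probability proportional to the
number of valid start positions; a `mode = "same"` flag restricts
placement to the original chromosome. Distances follow
`GenomicRanges::distanceToNearest` semantics (0 for overlapping or
book-ended intervals). The comparison uses our own rank-sum test with
midranks, tie-corrected variance and continuity correction, switching to
exact enumeration below a combined sample size of 12 without ties; the
test suite cross-checks both paths against `stats::wilcox.test` and a
full labeling enumeration.

# The synthetic-data generator

`simulation_config()` defines the study conditions all acceptance
properties are evaluated under. Defaults: 20 genes on 2 synthetic
chromosomes with 10–20 kb intergenic gaps, 1–3 isoforms per gene
(30/40/30%), 15% single-exon genes, 5 tissues × 2 replicates, 30% of
transcripts expressed in exactly one tissue and the rest in all tissues,
log-normal per-transcript mean counts (meanlog log 60, sdlog 0.5) with
negative-binomial replicate noise (size 20) — about 20,000 reads in
total, with a mean read length near the 759-base regime of the
experiment type being emulated (the 20-gene mixture is coarse, so
individual seeds range roughly 650–950). Degradation truncates 30% of
reads at the 5' end by a geometric number of bases (mean 250); splice
boundaries get discretized Gaussian jitter with sd 0.5 bp (most
junctions exact, occasional 1–2 bp wobble, as spliced aligners produce);
terminal ends get sd 8 bp; intronic/intergenic single-exon noise reads
are added at 2% of the genic read count. One tenth of transcripts are
withheld from the public reference as novel isoforms and one tenth of
genes as novel loci.

Two generator rules exist purely for identifiability, and are design
constraints rather than tuning:

* no isoform's intron chain is a 3'-terminal subsequence of a
  sibling's (retained introns are never terminal, alternative first
  exons get their own donor) — such isoforms are provably unrecoverable
  under degradation-aware collapse;
* isoforms with the same intron count differ by more than 30 bp at some
  boundary — chains closer than the 20 bp clustering tolerance plus
  jitter would be merged into one cluster by any assignment rule.

What the generator does **not** emulate: base-level sequences and
sequencing error, alignment artifacts, barcode bleed-through,
quality-score filtering, internal priming, and expression correlation
structure between tissues. Passing the recovery and accuracy suites
therefore demonstrates the correctness of the coordinate-level
algorithms under the stated noise model, not end-to-end performance on
real nanopore data.

# Numerical choices and degenerate inputs

* Medians use the lower-middle value on even counts (deterministic).
* Empty read sets cluster to an empty output, not an error; an all-empty
  cluster stage stops the builder with a clear message.
* EM with zero assigned reads returns an empty vector with a warning;
  all-zero TSI vectors are skipped and logged via an attribute.
* `rank_sum_test` returns p = 1 when all values are identical.
* The shuffle reports an interval as unplaceable after 10,000 rejections
  rather than looping forever.
* Problem sizes in tests and acceptance runs are the generator defaults
  above (~20k reads, 20 genes); oracle-equivalence suites use 200+
  random instances of at most a few transcripts each. These sizes were
  chosen so a complete validation run finishes in a couple of minutes on
  a laptop.

# Known limitations

* Collapse absorbs genuine short isoforms that look like degradation
  products; this is intrinsic to the method, not an implementation
  limit.
* Class-code semantics for `m`/`n` versus older vocabularies differ
  subtly between versions of the reference comparison tool; ours are
  fixed, documented, and oracle-tested, but may not byte-match any
  specific external version on edge cases.
* Compatibility-based quantification has no analogue of a mapping
  quality threshold; reads compatible with nothing are reported, never
  force-assigned.
* The locus-grouping tolerance (100 bp on 3' ends) is our reuse of the
  collapse 3' tolerance, not a documented constant of the original
  procedure.
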