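---
title: "Transcriptome structure from RNA-Seq alignments: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome structure from RNA-Seq alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarsplice)
```

# Scope

`tarsplice` implements the post-alignment computations used to characterize a
transcriptome against a reference genome in an unreplicated, multi-stage
RNA-Seq design of the kind used for fungal developmental series (e.g. mycelium
sampled at three cultivation times, 90 nt reads): mapping statistics, RPKM
quantification with a transcriptional-activity cutoff, transcription active
region (TAR) detection, intergenic novel-transcript discovery, gene-boundary
refinement, four-type alternative-splicing (AS) classification, pairwise
differential expression without replicates, and GO-term enrichment. A
synthetic-data generator plants ground truth for every rule so that each stage
is testable by parameter recovery.

All internal coordinates are 0-based half-open; conversion to the 1-based
inclusive conventions of GTF happens only at I/O boundaries. Splice junctions
are *inputs* (from a spliced aligner or from the generator): the package does
not align reads. Libraries are treated as unstranded; annotation strand is
used only for 5'/3' reporting.

# Quantification and activity calling

RPKM is the classical `1e9 * C / (N * L)` with `C` the unique-mapping read
count for the gene, `N` the total mapped reads of the library and `L` the
summed exon length. Only unique-mapping reads (a single genomic placement)
are counted, for consistency with the coverage-based rules below.

The activity cutoff — the RPKM below which a gene is considered
transcriptionally silent — is specified in the source protocol only as a "95%
interval over RPKM values", which does not pin down an estimator. The default
here is the empirical 2.5th percentile of the *positive* RPKM values, applied
globally: it is assumption-free, reproducible, and monotone in the data. A
normal-theory variant (`mean - 1.96 sd`) is selectable via
`activity_cutoff(method = "normal")`. Genes at or above the cutoff are active.
With all-zero input the cutoff degenerates to 0 and every gene is flagged
inactive with a `degenerate` marker.

# TARs, novel transcripts and boundary refinement

A TAR is a maximal run of bases at depth `>= min_depth` (default 2), with
runs separated by at most `max_gap` (default 0) bp merged. TARs overlapping
no annotated gene are candidate novel transcripts when all three rules hold:

* **length**: strictly greater than 150 bp (strict because the rule is
  worded as "more than");
* **distance**: every annotated gene boundary at least 200 bp away
  (boundary-to-boundary, inclusive at 200);
* **expression**: mean depth above the local background *and* above
  `min_depth`, where background is the mean all-reads depth over 1 kb
  windows flanking the TAR with genic bases excluded. The window size is a
  convention (the protocol says only "above the surrounding intergenic
  region") and is configurable.

Boundary refinement walks outward from each annotated gene end while depth
stays at or above `drop_fraction` (default 0.2) of the depth at the annotated
boundary. A "sharp reduction" is quantified as a drop below that threshold
sustained for at least 10 bp (`sustain`), so single-base dips do not end an
extension. Walks are capped at `max_extension` (default 2000 bp, bounding
runaway extension into unannotated transcription) and at the nearest
neighboring gene, so refined intervals never overlap a neighbor's annotated
span. Genes whose annotated span overlaps another gene are excluded outright,
with a reason string. On clean rectangular signal the recovered extension
equals the planted one exactly; the acceptance suite checks 0/50/100/500 bp.

Mate pairs link TARs into potential multi-TAR gene models: an edge between
two TARs is the number of read pairs with one mate overlapping each, edges
below `min_pairs` are dropped, and connected components (via igraph) are
reported, singletons included.

# Alternative-splicing classification

Junctions record the last exonic base upstream (donor) and the first exonic
base downstream (acceptor), 0-based; the implied intron is
`[donor + 1, acceptor)`. A junction belongs to a gene iff both ends fall
within the gene span; junctions touching two genes are assigned to neither.

* **Exon skipping**: a junction whose donor matches the annotated donor of
  exon *i* and whose acceptor matches the annotated acceptor of exon *j*,
  with *j >= i + 2* in genomic order. The match is exact by default
  (`tolerance = 0`), since the rule is annotation-anchored.
* **Intron retention** between two consecutive exons requires all five of:
  the intron's own junction present; >= 90% of intron bases covered by
  unique-mapping reads; mean intron depth >= 15% of the larger of the two
  flanking exons' mean depths; all bases of the 5 bp windows immediately
  inside and outside both intron boundaries covered; and no other gene
  overlapping the intron. Both 90% and 15% are inclusive thresholds. "Depth
  of Exon1 or Exon2" is read as "the larger of the two suffices"
  (`exon_combine = "max"`, with `"min"` selectable) and depth is summarized
  by the mean (`"median"` selectable).
* **A5SS / A3SS**: two junctions of one gene sharing their acceptor but
  differing in donor give an alternative-5'-splice-site event; sharing the
  donor but differing in acceptor, an A3SS event. Labels follow the genomic
  (plus-strand) convention, appropriate for an unstranded library;
  `use_strand = TRUE` swaps labels on minus-strand genes. Events are
  deduplicated by (gene, type, anchor coordinates).

Note that a skipping junction also forms donor-sharing and acceptor-sharing
pairs with the canonical junctions it bypasses, so a planted ES event
genuinely implies A5SS/A3SS events under these rules; the generator's
expected-event enumeration accounts for this.

# Differential expression without replicates

With one library per stage, the test operates on the two counts of each gene.
The Audic–Claverie count model is used in its symmetrized conditional form:
under the null of equal rates, `y` given the total `s = x + y` is
`Binomial(s, N_B / (N_A + N_B))`. The two-sided p-value sums the
probabilities of all splits no more likely than the observed one (the
minimum-likelihood convention of exact tests), computed exactly via a
vectorized unimodal search rather than full enumeration. This form was chosen
over the raw posterior-predictive tail because it is *exactly* invariant
under swapping the two stages (the implementation canonicalizes the
orientation so swapped calls are bitwise identical) and gives p = 1 for equal
counts in equal libraries. FDR control is Benjamini–Hochberg
(Benjamini–Yekutieli selectable); calls are made at FDR <= 0.001 by default
and classified up/down by library-size-normalized rates. The fold change
reported for display uses a pseudocount of 1 read; the pseudocount never
enters the test. Genes with zero counts in both libraries are excluded from
calling.

GO enrichment is the one-sided hypergeometric tail per term with BH
adjustment across terms; terms with no annotated genes in the universe are
skipped.

# The synthetic-data generator

`sim_config()` fixes the study conditions: one 250 kb contig, 30 genes of 2-5
exons (120-300 bp exons, 100-250 bp introns, 0.9-1.5 kb intergenic gaps),
three stages labelled 3d/6d/9d, 90 nt reads in abutting mate pairs (180 bp
fragments, so both mates tile the fragment without an internal gap), per-gene
depth 30 (a divisor of the read length, so clean-mode lattice steps are
integral). Planted features, one role per gene:

* nine intergenic units on the grid lengths {120, 151, 300} bp x distances
  {100, 200, 250} bp at depth 18, exercising both sides of the strict-150 and
  inclusive-200 rules;
* UTR extensions of {0, 50, 100, 500} bp on the genomic right end;
* three intron-retention introns (forced intron length 300 bp) with planted
  coverage fraction / depth ratio (1.0, 0.5), (0.6, 0.5), (1.0, 0.05) — one
  detectable, one failing the 90% rule, one failing the 15% rule;
* two skipping junctions, two alternative-donor and two alternative-acceptor
  junctions (support 5);
* five stage fold changes of 2x / 0.5x in stage 6d;
* one deliberately overlapping gene pair, to exercise exclusion rules.

In **clean mode** (default) reads are placed on a deterministic lattice:
`depth` stacked copies of a step-90 tiling with the final read pinned at the
transcript end, giving exactly rectangular coverage inside the transcribed
span and zero outside. This makes boundary-anchored recoveries exact, which
is what the recovery tests assert. In **stochastic mode** read counts are
Poisson and positions uniform along the mature transcript; planted intronic
reads overhang exon-intron boundaries as unspliced pre-mRNA fragments do.
Detectability flags in the manifest are derived from the planted parameters
and the rule thresholds; they are exact guarantees only for clean signal, and
under noise a feature planted exactly at a threshold (e.g. a 151 bp unit
against the strict `> 150` rule) genuinely straddles it.

Planted fold changes default to 2x/0.5x rather than something larger because
the toy genome has only ~30 genes: a strong fold change on several
high-count genes shifts the library totals enough that every null gene's
*relative rate* genuinely changes under total-count normalization — a
composition effect, not a defect of the test. For the same reason
`evaluate_recovery()` scores the DEG class only on stochastic simulations;
deterministic counts violate the count model's sampling assumptions and any
total shift becomes "significant" at infinite precision. Power and null
calibration of the test itself are assessed in a dedicated count-level
simulation (5000-gene null, 8-fold changes at mean depth 100 across 1000
genes), where composition is negligible.

Quantities the paper-scale study reports that depend on the full sequencing
dataset (tens of millions of reads, thousands of unigenes, database-dependent
annotation) are out of reach at these problem sizes; the package therefore
validates *rules and estimators*, not dataset-scale counts. Passing tests
show the filters and tests behave exactly as specified on data satisfying the
generator's assumptions (uniform placement, no sequencing error, no GC or
positional bias); they do not certify behavior under real-library biases.

# Numerical and degenerate-input conventions

* Quantile type for the percentile cutoff is R's default (type 7); the test
  suite pins it against an interpolation oracle.
* `ac_test` caps p-values at 1; ties in the minimum-likelihood set are
  resolved with a relative tolerance of 1e-7, as in `fisher.test`.
* Coverage vectors are plain integer arrays per contig; blocks outside the
  contig are an error naming the read.
* Empty inputs (no junctions, no reads, zero depth) yield empty but
  well-formed tables, never errors.
* A gene whose boundary base has zero depth is never extended.

# Problem sizes

The bundled simulations use a 250 kb contig, 31 genes and ~8000 reads per
stage; the DEG calibration uses 50 simulations of 5000 genes. These sizes
were chosen so that every planted feature class is represented several times
and the full simulate-analyze-evaluate chain runs in seconds, which keeps
property-style tests (multiple seeds, hundreds of randomized fixtures)
practical.
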