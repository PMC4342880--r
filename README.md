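# tarsplice

Post-alignment transcriptome-structure analysis for unreplicated, multi-stage
RNA-Seq — the setting typical of fungal developmental series where one
library is sequenced per cultivation stage and the questions are structural:
which genes are transcriptionally active, where is there transcription
outside the annotation, how far do real transcript ends extend past annotated
boundaries, which genes splice alternatively, and which genes change between
stages.

The package implements, as composable R functions over plain data frames:

* **Mapping statistics** — unique vs multi-position matched reads, perfect
  (zero-mismatch) matches, gene coverage fractions from unique-mapping
  coverage, and the relative-position read distribution along genes.
* **Quantification** — RPKM (`10^9 C / (N L)`: count per kilobase of exon
  model per million mapped reads) and a transcriptional-activity cutoff taken
  from a 95% interval over the RPKM distribution (empirical 2.5th percentile
  of positive values by default).
* **TARs and novel transcripts** — transcription active regions as maximal
  covered runs; intergenic TARs become novel-transcript candidates when
  longer than 150 bp, at least 200 bp from any annotated gene, and expressed
  above the flanking intergenic background.
* **Gene-boundary refinement** — 5'/3' extension of annotated genes up to the
  point of sharp read-signal reduction (depth falling below 20% of the
  boundary depth, sustained ≥ 10 bp), capped at neighbors; overlapping genes
  excluded. Mate pairs link TARs into multi-TAR gene models.
* **Alternative splicing** — junction-anchored classification of exon
  skipping (ES), intron retention (IR: five conditions — junction present,
  ≥ 90% intron coverage, intron depth ≥ 15% of the flanking exon depth, 5 bp
  windows covered at both boundaries, no overlapping gene), alternative 5'
  and 3' splice sites (junction pairs sharing one end).
* **Differential expression without replicates** — the Audic–Claverie exact
  count test in its symmetrized conditional form (binomial on the count sum),
  Benjamini–Hochberg FDR, up/down classification at FDR ≤ 0.001, and
  hypergeometric GO-term enrichment.
* **Synthetic data with planted truth** — a generator that emits gene models,
  SAM alignments, junction BEDs and stage-wise counts with planted IR / ES /
  A5SS / A3SS events, intergenic units, UTR extensions and fold changes, plus
  an evaluator scoring recovery against the truth manifest.

Standard formats are supported at the boundaries: GTF/GFF3 and BED12 gene
models, SAM (or a documented TSV dialect) alignments, BED6+1 junctions.

## Worked example

Simulate a three-stage experiment with planted ground truth, run the full
pipeline, and score recovery:

```r
library(tarsplice)
sim <- simulate_experiment(sim_config(seed = 1))
res <- run_pipeline(sim)
print(res)
#> pipeline result over 3 stage(s)
#>   stage genes_with_as n_events ES IR A5SS A3SS fraction_genes_as ir_fraction
#> 1    3d             7       11  2  1    4    4         0.2258065  0.09090909
#> 2    6d             7       11  2  1    4    4         0.2258065  0.09090909
#> 3    9d             7       11  2  1    4    4         0.2258065  0.09090909
#>       pair n_up n_down
#> 1 3d_vs_6d    3      2
#> 2 3d_vs_9d    0      0
#> 3 6d_vs_9d    2      3
```

Seven of the 31 simulated genes carry the planted splicing events (22.6% of
genes, 11 events per stage), and the five genes planted with 2-fold /
0.5-fold changes in stage 6d are the only differential calls. Recovery
against the truth manifest:

```r
evaluate_recovery(res, sim)
#>              class n_truth n_called tp fp fn sensitivity precision
#> 1               IR       1        1  1  0  0           1         1
#> 2               ES       2        2  2  0  0           1         1
#> 3             A5SS       4        4  4  0  0           1         1
#> 4             A3SS       4        4  4  0  0           1         1
#> 5            novel       4        4  4  0  0           1         1
#> 6        extension       4        4  4  0  0           1         1
#> 7 overlap_excluded       2        2  2  0  0           1         1
```

Every detectable planted feature is recovered with no false calls: of the
nine planted intergenic units only the four satisfying length > 150 bp and
distance ≥ 200 bp are reported; UTR extensions of 0/50/100/500 bp are
recovered exactly; the deliberately overlapping gene pair is excluded from
boundary refinement. Individual stages are available under `res$stages`, e.g.
the differential calls:

```r
head(subset(res$deg[["3d_vs_6d"]]$results, call != "ns"))
#>         gene_id count_a count_b log2_fold_change          fdr call
#> gene023 gene023     360     720        0.8913363 1.110326e-21   up
#> gene024 gene024     180     360        0.8893450 3.036843e-11   up
#> gene026 gene026     420     210       -1.1032414 8.749103e-20 down
```

A minimal quantification check: `compute_rpkm(c(gA = 10L), c(gA = 1000L),
1e6)` returns `10` — 10 reads on a 1 kb exon model in a million-read library
is 10 RPKM by definition.

A thin command-line wrapper is installed at `inst/cli/tarsplice.R`
(`Rscript tarsplice.R {simulate|run} --seed N --out DIR`).

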