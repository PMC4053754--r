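# txdominance

Most protein-coding genes are annotated with many transcript isoforms, but
in any one condition their expression is rarely spread evenly across them.
`txdominance` implements a transcript-dominance analysis for bulk and
single-compartment RNA-seq: given a GENCODE-style annotation and
transcript-level quantifications, it identifies each gene's **major**
transcript (the highest-expressed isoform), classifies **dominant** majors,
accounts for the share of the mRNA pool they explain, tracks how often the
same major recurs across samples, detects **switch events** between
conditions, validates calls against splice-junction read evidence, and
characterises the non-coding (retained-intron / processed-transcript)
majors of protein-coding genes. A synthetic-data generator with the same
statistical structure makes the entire pipeline runnable and testable with
no external downloads.

It is written for transcriptomics analysts who want reproducible
major-isoform calls and switch detection on top of any quantifier's FPKM
output, without re-running heavyweight isoform-deconvolution machinery.

## Definitions

With expression in FPKM (fragments per kilobase of feature per million
mapped reads, `FPKM = count x 10^9 / (length_nt x library_size)`):

- A gene is **expressed** when its exon-based expression — the mean FPKM of
  its expressed exonic features — is above 1 FPKM (configurable; 5 and 10
  FPKM sweeps are built in).
- The **major** transcript of an expressed gene in a sample is its
  highest-FPKM isoform; it is **x-fold dominant** when
  `expression(major) / expression(runner-up) >= x`, with x = 2 and 5 the
  conventional thresholds.
- The **mRNA-pool fraction** of a transcript class is its FPKM-mass share
  of all transcripts of the protein-coding study set (genes with every
  annotated transcript >= 300 nt; mitochondrial genes excluded).
- A gene undergoes an **x-fold switch** between transcripts I_k, I_l and
  samples S_i, S_j when it is expressed in both samples and
  `expr(I_k)/expr(I_l) >= x` in S_i while `<= 1/x` in S_j. The switch is
  **strong** when each sample's dominating transcript is >= 5 FPKM there
  while the reciprocal one is < 1 FPKM.

## Worked example

Simulate a 500-gene dataset (4 transcripts per gene, one carrying 80% of
the gene's output; 17% of genes with a non-coding major; 5 planted strong
switches across 4 samples) and run the full analysis:

```r
library(txdominance)

cfg <- pipeline_config(simulate = list(
  n_genes = 500, n_samples = 4, n_switches = 5,
  fraction_noncoding_major = 0.17, seed = 1))
report <- run_pipeline(cfg)
report
#> <txdom_report> 500 study genes, 4 samples
#>   mean major pool fraction: 0.798

glance(report)
#> # A tibble: 1 x 8
#>   n_study_genes n_samples mean_fraction_major mean_transcripts_per_gene_ratio ...
#> 1           500         4               0.798                            1.82

report$scans$x2
#> <switch_scan> x = 2
#>   15 events over 6 sample pairs; 15 strong
#>   5 of 477 genes involved

validate_against_truth(report)$metrics
#> # A tibble: 1 x 5
#>   major_accuracy n_compared switch_recall strong_switch_gene_precision ...
#> 1              1       1908             1                            1
```

The major transcripts carry 79.8% of the study-set mRNA pool — the
generator assigned them 80% — and every planted switch is recovered: the 5
switch genes each produce a strong event in the 3 sample pairs that contain
the perturbed sample, hence 15 events. `tidy(report)` returns the per-gene
dominance calls; `autoplot(report)` draws the rank-abundance profile;
`report$pool`, `report$sweep`, `report$recurrence`, `report$biotype` and
`report$ri_positions` hold the per-module tables. Real data enter through
`pipeline_config(inputs = list(gtf = ..., transcript_fpkm = ...,
exon_counts = ..., library_sizes = ..., metadata = ...))` with the TSV
layouts described in `?read_count_table`.

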