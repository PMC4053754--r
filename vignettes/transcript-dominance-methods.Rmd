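---
title: "Methods: major transcripts, dominance and switch events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: major transcripts, dominance and switch events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txdominance)
```

## The analysis model

`txdominance` asks a simple question of a quantified transcriptome: within
each protein-coding gene, how unevenly is expression distributed across the
annotated isoforms? The analysis works on two parallel expression tracks:

* **Gene expression** is estimated from exonic features: the mean FPKM over
  the gene's *expressed* exon bins (disjoint pieces of the exon union).
  This deliberately does not equal the sum of transcript FPKMs — exon-based
  estimates are robust to isoform-deconvolution errors, and the
  transcripts-to-genes expressed ratio can consequently fall below 1.
* **Transcript expression** comes from an external quantifier (any tool
  emitting transcript FPKM) or, for synthetic data, from the generator's
  quantifier emulation.

A gene passes into the per-sample analysis when its exon-based FPKM is
strictly above the expression gate (default 1 FPKM, the level conventionally
associated with detectable protein); given that, every transcript of the
gene is ranked regardless of its own level. The top-ranked transcript is the
*major*; the ratio to the runner-up defines *x-fold dominance* with
`fold_ratio >= x`, so a single expressed isoform (infinite ratio) is
maximally dominant at every x.

Pool accounting works on FPKM mass: the fraction of the summed FPKM of all
study-set transcripts contributed by majors, by the two- and five-fold
dominant subsets, and by non-coding majors. Mitochondrial genes are removed
from numerator and denominator — they are present in many copies per cell
and a handful of their transcripts can otherwise absorb half the pool.

## Annotation model

The GTF is parsed into linked tables of genes, transcripts, exons and CDS.
Internally all coordinates are 0-based half-open; conversion happens only at
the GTF/BED boundary. The *study set* keeps protein-coding genes whose every
transcript is at least 300 nt (shorter transcripts are lost to library size
selection; the rule is strictly "shorter than", so a 300-nt transcript
passes). Derived quantities:

* **Introns** are maximal intervals inside the gene span overlapped by no
  exon of any transcript. The span is the gene's min-exon-start to
  max-exon-end; where transcripts do not reach the annotated gene
  boundaries, the exon-union span is the natural reading of "genic
  boundaries" and is what we use.
* **TSS groups** collect transcripts sharing the strand-aware 5'-most
  exonic base, by exact coordinate equality (no fuzz window): dominance
  within a multi-transcript TSS group isolates splicing from differential
  promoter usage.
* **Unique junctions**: a junction — identified by (chrom, donor = exon
  end, acceptor = next exon start, strand) — is unique to a transcript when
  exactly one transcript of the gene contains it. Genes whose transcripts
  all own at least one unique junction are *fully identifiable* and admit a
  quantifier-free major call from junction read counts (averaging counts
  when a transcript has several unique junctions; argmax ties yield no
  call, keeping the junction-vs-quantifier comparison conservative).
* **Length flags** mark the longest transcript and longest CDS per gene by
  strict maximum, ties flagging all maxima.

## Switch events

For a sample pair (S_i, S_j) the candidate transcript pair is the two
samples' major transcripts; an event is emitted when the expression ratio
of the pair is at least x in S_i and at most 1/x in S_j. A zero denominator
with positive numerator counts as infinite (passes the >= x side only);
0/0 never produces an event. Detection is symmetric: scanning (S_j, S_i)
yields the mirrored event.

Annotations on each event:

* **strong** — each sample's dominating transcript at >= 5 FPKM there while
  the reciprocal transcript is < 1 FPKM (boundaries exactly as stated:
  inclusive above, strict below). A strong switch automatically satisfies
  the five-fold ratio conditions, since 5/1 = 5.
* **expression dependent** — the gene's absolute expression difference
  between the two samples exceeds the mean of that difference over all
  genes expressed in both samples of the pair. "The mean" is ambiguous as
  to its reference population; the per-pair all-genes mean is this
  package's documented choice.
* Switch profiles report per-sample log ratios in **log base 2** (the log
  base is otherwise unspecified in common usage; log2 makes fold units
  legible), with an `NA` sentinel when either transcript is silent.
* The coding-change subset keeps strong events whose transcripts both have
  a CDS and whose CDS genomic-interval sets differ — a proxy for a protein
  change that requires no translation; same-CDS (UTR-only) pairs are
  excluded.

An exhaustive scan over all transcript pairs rather than the two majors
would find additional minor-isoform switches; restricting to majors matches
the analysis focus (changes in the dominating isoform) and keeps the event
table interpretable.

## Non-coding majors and retained introns

"Non-coding" is operationalised as zero annotated CDS. Major transcripts
are classed by their annotation biotype (protein_coding, retained_intron,
processed_transcript, nonsense_mediated_decay, other), with counts and
FPKM-mass fractions per class; the class masses recompose the overall
major-pool fraction exactly.

Locating a retained intron deserves a note. Under the all-transcript intron
definition above, the retained region of an annotated retained-intron
transcript is never intronic — that transcript's own exon covers it. The
retained region is therefore identified as the overlap between the major's
exon union and the intron complement derived from the gene's *other*
(non-retained-intron) transcripts; when several regions qualify, the widest
is used, ties resolved to the most 3'. Its midpoint is mapped strand-aware
onto the gene span (0 = transcriptional start, 1 = end), so mirroring a
gene maps position p to 1 − p. Positions are summarised by quartiles, split
by cellular compartment when metadata provide one.

## The synthetic generator

The generator emulates the statistical structure this analysis assumes,
not the read-level physics of sequencing:

* Each gene has K transcripts (default 4) over a shared scaffold of K + 2
  exons (default 200 nt exons, 150 nt introns); transcript k skips internal
  exon k + 1, giving every transcript one unique junction and every pair of
  transcripts distinct CDS (CDS covers the internal exons of each chain).
  All transcripts are >= 300 nt by construction.
* **Dominant scenario**: the designated major carries proportion p = 0.8 of
  the gene's output, the rest split evenly — a true fold ratio of 12 at
  K = 4. **Uniform scenario**: symmetric Dirichlet(alpha = 10) draws per
  gene and sample. These are the two hypotheses the pipeline must
  discriminate; p and alpha are the scenario defaults throughout the test
  suite.
* Gene totals are log-normal (meanlog 2, sdlog 1 in natural log), putting
  the bulk of genes between roughly 1 and 50 FPKM — a realistic expressed
  range with a tail below the 1-FPKM gate.
* Counts are **feature-level Poisson** draws around the FPKM-inversion
  expectation (exact expectations in noiseless mode, where the integer
  count invariant is deliberately relaxed); junction features use a fixed
  75-nt read-span length, introns default to zero signal plus an optional
  leakage fraction of gene expression, doubled in nucleus samples to
  emulate incomplete splicing. Read-level simulation (fragment length,
  positional bias, mapping ambiguity) is intentionally out of scope: every
  statistic the pipeline computes is a function of feature-level counts.
* **Planted switches** rescale a coding gene to 10 FPKM total and exchange
  two transcripts' shares in one sample of a chosen pair, which satisfies
  the strong-switch bounds by construction (0.8 x 10 = 8 >= 5;
  0.067 x 10 = 0.67 < 1). A planted gene also produces genuine events
  against the unperturbed samples — tests therefore check recall against
  the registry and require all strong-switch genes to be planted ones.
* **Non-coding majors**: a designated fraction of genes make their major a
  retained-intron or processed transcript (default split 50/50). The
  retained intron is the scaffold intron whose strand-aware midpoint lies
  nearest the target relative position (default 0.8, the 3'-ward bias);
  because positions snap to the scaffold, the registry records the
  *realised* position and recovery tests compare estimates to it rather
  than to the nominal target.

What passing tests on this generator do **not** show: robustness to
quantifier-specific biases (the emulation is unbiased Poisson), to
mis-annotation, or to genes whose isoform structure departs from the
shared-scaffold model (nested genes, antisense overlap, many TSSs).

## Numerical choices

* "Expressed" is always *strictly greater than* the threshold; an exon is
  expressed at FPKM > 0 (the averaging rule needs some definition of an
  expressed exon; > 0 is the least restrictive one).
* FPKM ties for the major are broken lexicographically by transcript id and
  flagged, making reruns deterministic.
* Fold ratios with a silent runner-up are `+Inf`; a gene above the gate
  whose transcripts are all zero yields a flagged no-call.
* Relative abundances of a zero-total gene-sample are `NA` with a
  `zero_gene` flag rather than silently 0.
* Reports serialise floats at 6 significant digits and order rows
  deterministically, so identical inputs give byte-identical outputs.

## Problem sizes

The test-suite study conditions are: 1,000 genes for noiseless and
Poisson-noise (5M reads) dominance recovery; 5,000 genes for the
uniform-scenario Monte-Carlo comparison (40,000 oracle draws); 1,000 genes
per scenario for discrimination; 300 genes / 6 samples / 20 events for
switch recovery; 500 genes for junction concordance and retained-intron
position recovery. These sizes put Monte-Carlo error well inside the stated
tolerances while keeping the suite fast.

## Known limitations

* Table-style dominance percentages are reported as exact per-sample
  ratios of the counts in the same row; published tables of this kind are
  sometimes per-sample averages whose cells do not reproduce from one
  another, and no attempt is made to match such cells.
* The expression-dependence flag depends on the per-pair mean definition
  above; other reference populations would shift the split.
* Junction-based validation is restricted to fully identifiable genes by
  design; genes outside that set are validated only through the quantifier
  track.
* The protein-change proxy (CDS interval inequality) cannot detect events
  that preserve CDS intervals but alter translation indirectly.
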