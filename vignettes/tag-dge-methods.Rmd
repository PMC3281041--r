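---
title: "Tag-based DGE profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based DGE profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagDGE)
```

## The measurement model

Tag-based digital gene expression (DGE) counts short restriction-anchored
cDNA tags instead of whole reads. In the NlaIII/MmeI protocol, oligo-dT
beads capture the mRNA 3' end, NlaIII cuts at every CATG, the 3'-most
fragment is retained on the beads, and MmeI — whose recognition site is
engineered into the ligated adaptor — cuts 17 bp downstream of the CATG.
The observable unit is therefore a 21-nt *tag*: the CATG anchor plus 17 nt
of transcript sequence. A library is a multiset of such tags; a gene's
expression is the number of tags that identify it, normalized per million
clean tags (TPM).

`tagDGE` implements the full analysis path: virtual-tag reference
construction, raw-library cleaning, tag-to-gene mapping with one-mismatch
tolerance, TPM quantification, exact-test differential expression,
hypergeometric term enrichment — plus a protocol simulator that generates
libraries with per-tag ground truth so every stage is testable without any
external data.

## Virtual tag reference and mapping

`buildTagIndex()` enumerates **every** CATG+17-nt window of every reference
transcript, not only the 3'-most: internal sites and incomplete digestion
produce real tags, and the reference must catch them. Windows with fewer
than 17 nt downstream yield no tag (the MmeI cut would run off the
fragment); windows containing N are skipped. Tags shared by several genes
are merged into a single entry flagged *ambiguous*.

`mapTag()`/`mapLibrary()` allow at most one mismatch, counted over the
17-nt variable region only — the CATG anchor is enzymatically defined, and
a read with a corrupted anchor would never have been recognized as a tag.
Exact matches take precedence over one-mismatch matches, and ambiguity is
judged within the best distance stratum only, so an exact unique hit is
never discarded because a one-mismatch neighbour exists elsewhere. The
category precedence is gene > genome > unknown: a tag matching both a gene
tag and a genome 21-mer is gene-mapped, and the genome category counts the
remainder only, so the three categories partition the clean library. All
per-gene quantification uses *unambiguous* tags; a tag hitting several
sites of one gene still counts once toward that gene, because ownership,
not site, defines ambiguity.

## Cleaning rules

`cleanRawTags()` applies the conventional filters in a fixed order:
adaptor-only (empty) records, then reads containing N, then structurally
malformed reads (wrong length, missing anchor, non-ACGT characters —
counted in their own bucket, never silently dropped), and finally tags
whose total copy number is 1. Singleton status is judged on aggregated
sequence counts after the structural filters, since artifacts have no
sequence identity; copy-number-1 tags are overwhelmingly sequencing-error
variants. The bucket copy counts sum exactly to the raw total — an
invariant the test suite asserts against the simulator's per-tag
provenance. Reported percentages are rounded half-up to two decimals, the
convention of published tag-library statistics tables.

## TPM

`computeTPM()` uses `tpm = copies * 1e6 / cleanTotal` with the clean-tag
total of the library as denominator — all clean tags, not only the mapped
ones, following the standard definition of "transcripts per million clean
tags". No gene-length normalization is applied: the protocol yields one
tag per transcript molecule regardless of length. Genes with zero mapped
copies are retained with TPM 0, so library comparisons always share one
gene universe.

## The exact test for two count libraries

For a gene with count $x$ in a library of $N_1$ clean tags and $y$ in a
library of $N_2$, the Audic–Claverie conditional law of $y$ given $x$ is

$$p(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}},$$

a negative-binomial law with size $x+1$ and success probability
$N_1/(N_1+N_2)$ — a relation the unit tests exploit as an independent
cross-check via `pnbinom()`, while the implementation itself accumulates
the tail sums in log space (`acPValue()`), stable for counts up to $10^6$;
p-values below $10^{-300}$ are truncated to stay in $(0,1]$. The two-sided
p-value is the doubled smaller tail,
$\min\{1, 2\min(P(Y \le y \mid x), P(Y \ge y \mid x))\}$, capped at 1.

One property deserves emphasis: because the statistic conditions on the
*first* library's count, it is **directional** —
$p(x,y,N_1,N_2) \ne p(y,x,N_2,N_1)$ in general (they agree in order of
magnitude, and exactly when $x=y$ with $N_1=N_2$). `callDEGenes()`
therefore fixes one orientation for a comparison: the later stage is
always library B, and the log2 ratio is B over A, so "up" means
up-regulated at the later stage.

Calls combine two thresholds: significance (default FDR $q < 0.001$ from
`bhFDR()`, the Benjamini–Hochberg step-up; a raw-p mode `sigMode = "p"`
with $p \le 0.001$ is provided because both conventions appear in
published tag-DGE work) and effect size $|\log_2 \text{ratio}| \ge 1$.
The ratio uses library-size-normalized proportions (equivalent to the TPM
ratio) with a 0.5 pseudocount on both counts; the p-value always uses the
raw counts — the exact test handles zeros natively, only the ratio needs
regularization.

## Term enrichment

`hypergeomEnrichTerm()` evaluates the upper-tail hypergeometric
probability of observing at least $m$ term-annotated genes among $n$ DE
genes drawn from a universe of $N$ annotated genes, $M$ of which carry the
term, in log space; the tail includes $m$ itself, and $m=0$ returns
exactly 1. The background universe is the set of genes with at least one
annotation (not all detected genes). The multiplicity correction is
Benjamini–Hochberg by default — matching FDR-style thresholds used for
pathway-level calls — with Bonferroni selectable; significance defaults to
corrected $p < 0.05$.

## Validation statistics

`ddctFoldChange()` implements comparative-CT qPCR quantification:
$\Delta C_T = C_T^{target} - C_T^{reference}$ per sample,
$\Delta\Delta C_T$ relative to the *mean* control $\Delta C_T$ (the group
mean generalizes the single-control convention to replicated designs), and
fold change $2^{-\Delta\Delta C_T}$. `percentOfControl()` reports
knockdown effect sizes as $100 \cdot \bar{x}_{trt}/\bar{x}_{ctl}$ with a
two-sided Student's t-test (pooled variance by default, Welch selectable).

## What the simulator emulates — and what it does not

`simulateDGEExperiment()` generates, per configuration:

* a reference transcriptome of i.i.d. sequences (uniform lengths, fixed GC
  content, default 40% as typical for an insect transcriptome), each
  flagged for whether the protocol can observe it at all (a CATG with
  $\ge 17$ nt downstream);
* per-gene relative abundances drawn log-normal with unit log-sd — a
  heavy-tailed profile in which a minority of genes carries most of the
  tags, as real libraries show — with a Bernoulli `deFraction` of genes
  multiplied by `deFoldChange` (up or down, equiprobable) from a random
  change-point stage onward;
* raw libraries of `depth` records: adaptor-only artifacts and
  N-containing reads at their configured rates, otherwise a tag from a
  gene sampled proportional to abundance *among taggable genes* (an
  untaggable transcript yields no NlaIII fragment and cannot contribute
  depth), carrying the gene's 3'-most tag with independent per-base
  substitution errors over the 17-nt variable region.

The emission side uses the 3'-most site only (bead precipitation retains
the 3' fragment), while the reference enumerates all sites — the
asymmetry of the real protocol. Singleton artifacts arise naturally from
error variants; there is no separate singleton-injection knob. Default
noise rates (substitution 0.1%/base, adaptor-only 0.5%, N reads 0.5%)
were chosen so the default library reproduces the composition of
published raw tag libraries, where clean tags are roughly 98% of raw
tags.

Not modelled: PCR amplification and GC bias, indel errors, quality-score
structure, incomplete digestion on the emission side, antisense tags, and
cross-gene sequence homology (transcripts are i.i.d., so ambiguous tags
are rare — real transcriptomes with gene families produce many more).
Consequently, passing recovery tests demonstrates correctness of the
*computational* path under the stated noise model, not robustness to
every artefact of real libraries.

Every emitted record carries exactly one provenance row
(gene / error variant / adaptor-only / N-contaminated), and the whole
experiment is a deterministic function of the configuration, including its
seed; stage-specific seeds are derived by fixed small offsets so the
transcriptome, the profiles and the libraries can also be regenerated
independently.

## Numerical choices and degenerate inputs

* Tail sums: log-space accumulation with `logSumExp`; the upper tail is
  summed adaptively in chunks until terms decay below a $10^{-17}$
  relative contribution.
* Rounding: percentages use half-up rounding at two decimals
  (`roundHalfUp()`), matching report conventions, rather than R's
  round-half-even.
* Zero denominators yield `NA` ("undefined"), never 0.
* Empty inputs are legal where a result is well-defined: an empty raw
  library cleans to empty with all-zero statistics; a sequence without
  CATG yields an empty tag list; an empty DE set gives every term $p=1$.
* Subsampling for saturation curves classifies each distinct tag once and
  reuses the classification across subsamples — identical to re-mapping,
  since a tag's mapping does not depend on its copy number; 3 seeded
  replicates are averaged per grid point.
* The saturation criterion is a growth-rate plateau (relative gain over
  the last grid doubling), since the detected-gene count itself is
  non-decreasing in depth.

## Problem sizes used by the test suite

The packaged checks run desk-scale versions of the study design: 2000-gene
references, two or three libraries of $5 \times 10^5$ raw tags, three
simulation seeds for the stochastic calibration checks (type-I control,
DE sensitivity and empirical FDR against ground truth), and a
$51 \times 51 \times 4$ grid of counts against an exact-rational oracle
for the exact test. These sizes were chosen so the whole suite completes
in about a minute on a laptop while keeping binomial confidence bands
tight enough to be informative.

## Known limitations

* The one-mismatch neighbourhood covers the variable region only; a tag
  whose sequencing error hit the anchor is unobservable by design.
* The genome side of mapping is 21-mer set membership, not alignment;
  spliced or coordinate-level reporting is out of scope.
* The exact test models sampling variance only; biological replicate
  dispersion (negative-binomial overdispersion across animals) is not
  modelled, as each library is a single pooled sample in this design.
* GO-style term ancestry is not propagated; annotations are opaque labels.

## Session info

```{r}
sessionInfo()
```
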