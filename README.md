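# tagDGE

Tag-based digital gene expression (DGE) profiling in R — the SAGE-style
NlaIII/MmeI protocol in which each transcript is represented by a 21-nt
tag (the 3'-most CATG site plus the 17 nt released by the MmeI cut), and
expression is measured by counting tags. The package was built for
transcriptomics of non-model organisms where such tag libraries are
compared across developmental stages — for example pheromone-gland
libraries sampled around adult eclosion in the silkworm — but every
component is generic.

It provides, as S4 classes and camelCase functions:

* **Virtual tag reference** (`buildTagIndex`): every CATG+17-nt tag
  derivable from each reference transcript, with gene ownership, ambiguity
  flags and one-mismatch lookup over the 17-nt variable region.
* **Library cleaning** (`cleanRawTags`): removal of adaptor-only records,
  N-containing reads, malformed reads and copy-number-1 tags, with exact
  copy bookkeeping and report-style statistics (`summarizeLibrary`).
* **Mapping** (`mapTag`, `mapLibrary`): gene > genome > unknown precedence,
  exact-before-one-mismatch, per-gene unambiguous tag counts.
* **Quantification** (`computeTPM`): transcripts per million clean tags;
  distribution (`expressionDistribution`) and saturation
  (`saturationCurve`) summaries.
* **Differential expression** (`acPValue`, `callDEGenes`): the
  Audic–Claverie exact conditional test. For counts x, y in libraries of
  sizes N1, N2 the conditional mass is

      p(y|x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) )

  with two-sided p = min(1, 2·min(P(Y ≤ y|x), P(Y ≥ y|x))), computed in
  log space; Benjamini–Hochberg FDR (`bhFDR`) and the thresholds
  FDR < 0.001 with |log2 ratio| ≥ 1 by default.
* **Enrichment** (`enrichAllTerms`): upper-tail hypergeometric test of DE
  gene sets against an annotated background universe,
  p = Σ_{i≥m} C(M,i)·C(N−M,n−i)/C(N,n), BH- or Bonferroni-corrected.
* **Validation statistics** (`ddctFoldChange`, `percentOfControl`):
  comparative-CT qPCR fold changes (2^−ΔΔCT) and knockdown effect sizes
  with Student's t-tests.
* **A protocol simulator** (`simulateDGEExperiment`): seeded reference
  transcriptomes, stage-wise expression with planted fold changes, and raw
  libraries with substitution errors, adaptor-only and N contamination —
  every emitted tag carries a provenance record, so recovery can be
  measured against ground truth.
* **Pipeline** (`runPipeline`): clean → index → map → TPM → pairwise DE →
  enrichment, writing auditably plain TSVs and a statistics report; a thin
  CLI wrapper lives in `inst/scripts/tagdge.R`.

## Worked example

Simulate a two-stage experiment with 10% of genes differentially expressed
at 4-fold, then run the analysis:

```r
library(tagDGE)

cfg  <- simConfig(nGenes = 500, depth = 100000L, nLibraries = 2L, seed = 7)
sim  <- simulateDGEExperiment(cfg)
cl   <- lapply(sim$libraries, cleanRawTags)
cl$lib1$stats
#> LibraryStats lib1
#>   raw 1e+05 (distinct 2,466) -> clean 97,609 (distinct 588)
#>   % of raw: clean 97.61, n_contaminated 0.50, adaptor_only 0.51,
#>   singleton 1.38, malformed 0.00
```

So of 100,000 raw tags, 97.61% survive cleaning; half a percent each were
adaptor-only or contained an N, and 1.38% were copy-1 sequencing-error
variants. Build the reference and call differential expression:

```r
idx  <- buildTagIndex(sim$genes)
idx
#> VirtualTagIndex: 2021 distinct CATG+17-nt tags ( 0 ambiguous ); 0 genome 21-mers
expr <- lapply(cl, function(x)
  expressionFromMapping(mapLibrary(x$clean, idx), x$clean, names(sim$genes)))
de   <- callDEGenes(expr$lib1, expr$lib2)   # orientation: lib2 over lib1
summarizeDECalls(de)
#> $up    [1] 28
#> $down  [1] 16
#> $total [1] 44
head(de[de$call != "ns", ], 2)
#>        gene   x    y log2Ratio        pValue        qValue call
#>    gene0002 325 1145  1.814923 4.294248e-107 5.367810e-105   up
#>    gene0014  48    4 -3.430313  7.018168e-11  8.997651e-10 down
```

44 genes pass FDR < 0.001 and |log2 ratio| ≥ 1; gene0002 rose from 325 to
1145 tag copies (log2 ratio 1.81). Against the simulator's ground truth,
all 44 calls are truly differentially expressed and only one planted gene
was missed:

```r
table(called = de$call != "ns", truly_de = deTruthLabels(sim$truth)[, 1] != "null")
#>        truly_de
#> called  FALSE TRUE
#>   FALSE   455    1
#>   TRUE      0   44
```

The same analysis end to end, with all intermediate TSVs and a report:

```r
runPipeline("results_demo", simConfig = cfg)
```

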