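# regenCompare

How similar is a regenerating brain to a brain tumor, transcriptome by
transcriptome? Adult zebrafish regenerate their telencephalon after a
stab lesion, passing through an early wound-healing stage (1 day
post-lesion, dpl), an early proliferative stage (3 dpl) and a
differentiation stage (14 dpl). Brain tumors — low-grade glioma (LGG)
and glioblastoma (GBM) — sustain many of the same programs
(proliferation, inflammation, angiogenesis) without ever terminating
them. regenCompare implements the comparative pipeline that puts this
question on a quantitative footing, and ships a synthetic-data
generator with known ground truth so every stage is testable without
any external download.

The pipeline, for audiences working on regeneration, cancer
transcriptomics, or cross-species comparison:

* **Differential expression** — negative-binomial Wald tests per
  two-group contrast with median-of-ratios size factors
  (`sizeFactorsMedianRatios`), trended method-of-moments dispersions,
  BH correction, and the Up/Down call at fold change > 1.5 (Down below
  the reciprocal, 1/1.5 = 0.67) and FDR < 0.05 (`runDE`).
* **Co-expression modules** — unsigned weighted network
  (s = |cor|, adjacency = s^β, β = 9), topological overlap, adaptive
  dendrogram decomposition with a minimum module size of 100 and a
  deep-split level, module eigengenes, and stage-specificity calls
  from eigengene z-profiles (`buildNetwork`, `detectModules`,
  `stageSpecificity`).
* **Ortholog resolution** — each zebrafish gene gets one human
  ortholog: high-confidence or name-matched candidates only, name
  matches first, then the lexicographic metric ranking (gene-order
  conservation, whole-genome-alignment coverage, reciprocal percent
  identities); multiply-claimed targets keep high-confidence pairs
  and are flagged for the asterisk annotation (`resolveOrthologs`).
* **Direction-stratified comparison** — Venn/UpSet arithmetic on
  Up/Down-tagged gene sets, the masked union log2-fold-change matrix,
  percent-unique summaries, and a stage-versus-cancer ranking by the
  signed Jaccard index (same-direction minus opposite shared genes,
  over the union) (`intersectDirectional`, `upsetExclusiveRegions`,
  `buildUnionMatrix`, `rankStageSimilarity`, `percentUnique`).
* **EASE enrichment** — the jackknifed one-tailed Fisher test (one
  query hit removed) against user-supplied GMT term collections, BH
  within category (`easeScore`, `enrichGeneSets`).
* **Synthetic data** — NB counts for the 4-group, n = 18 design with
  planted stage-specific DE genes and correlated module blocks, plus
  orthology tables and annotations with planted truth
  (`simulateCounts`, `simulateOrthology`, `simulateAnnotation`).

## Worked example

The whole analysis runs from one configuration; here at reduced scale
(3,000 genes, network on the 1,000 most variable):

```r
library(regenCompare)
cfg <- pipelineConfig(seed = 42, n_genes = 3000, wgcna_max_genes = 1000)
summary <- runPipeline(cfg)

summary$deg_counts$dpl1
#> $total 216   $up 152   $down 64

summary$modules$n                 # 6, all 6 stage-specific
unlist(summary$percent_unique)
#>  dpl1  dpl3 dpl14
#>  94.9  95.1  94.8

summary$similarity_ranking
#> [1] "dpl1"  "dpl3"  "dpl14"

summary$comparisons$dpl1_vs_LGG
#> shared 86, same direction 81, signed Jaccard 0.187
```

Reading the numbers: at 1 dpl the test calls 216 DEGs, skewed Up as
planted. Module detection finds six modules — the three planted
co-expression blocks plus modules formed by genes planted DE in the
same stage, which are genuinely co-expressed — and each is specific
to one stage. The similarity ranking recovers the planted
cross-species gradient (the simulated cohorts re-use 60% / 30% / 10%
of the dpl1 / dpl3 / dpl14 DE genes): 1 dpl is the most cancer-like
stage and 14 dpl the most distant. The percent-unique values are high
here because stages are planted independently; on real data they
measure how much of each stage's response is private to it.

A thin command-line wrapper writes all stage tables and a JSON
summary:

```sh
Rscript inst/scripts/run_pipeline.R --seed 1 --outdir pipeline_out
```

## Package layout

* `R/` — simulation, DE, co-expression, orthology, comparison,
  enrichment, QC and pipeline modules; S4 classes for the network,
  module, and orthology objects.
* `vignettes/comparative-pipeline.Rmd` — the methods vignette: models,
  parameter choices, numerical decisions, generator calibration,
  limitations.
* `tests/testthat/` — unit and property tests with independent
  brute-force oracles, plus the study-level acceptance suite.
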