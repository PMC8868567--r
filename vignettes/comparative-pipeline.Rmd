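---
title: "Methods: comparing a regeneration time course with tumor cohorts"
author: "regenCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing a regeneration time course with tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenCompare)
```

# Scope and data model

regenCompare implements the analysis shape used to ask how similar the
transcriptome of a regenerating brain is to that of brain tumors: a
zebrafish stab-lesion time course (uninjured control plus three
post-lesion stages, 1 / 3 / 14 days post-lesion, four or five
biological replicates each, n = 18) is profiled by bulk RNA-seq and
compared, through resolved human orthologs, against
tumor-versus-normal cohorts (low-grade glioma and glioblastoma). The
pipeline starts from integer gene-by-sample count matrices; alignment
and counting are upstream of this package.

Counts travel as a `SummarizedExperiment` with a `counts` assay and a
`condition` column; differential expression and enrichment results are
plain data frames; the network, module, and orthology objects are S4
classes (`CoexpressionNetwork`, `ModuleAssignment`, `OrthologyMap`)
with validity checks and accessors.

# Differential expression

Each contrast is two groups (a stage versus control, or tumor versus
normal). Normalization uses median-of-ratios size factors: the factor
of sample *j* is the median over always-expressed genes of
$K_{gj} / (\prod_j K_{gj})^{1/n}$, rescaled so the factors have
geometric mean one. When no gene is expressed in every sample the
estimator refuses and points to the total-count fallback
(`sizeFactorsTotalCount`).

Counts are modeled as negative binomial with
$\mathrm{var} = \mu + \alpha\mu^2$. Group means are estimated on the
normalized scale as $\hat\mu = \sum_j K_j / \sum_j s_j$; the reported
effect is $\log_2(\hat\mu_\text{trt}/\hat\mu_\text{ctl})$, the
standard error comes from the delta-method variance of the log ratio
under the NB law, and the Wald p-value is
$2(1 - \Phi(|\log_2\!\mathrm{FC}/se|))$. Genes are classified Up when
the fold change exceeds 1.5 at BH-FDR < 0.05, Down below the
reciprocal cutoff $1/1.5 = 0.67$ (always derived as the reciprocal,
never set independently), and NS otherwise. FDR is computed over the
full gene universe of the contrast.

Numerical choices:

* **Count floor.** When either group mean is zero, 0.5 is added to
  both normalized group means before the log ratio, so fold changes
  are finite; genes all-zero in both groups are reported as
  $(\log_2\!\mathrm{FC}, p) = (0, 1)$.
* **Dispersion.** The per-gene method-of-moments estimate
  $\hat\alpha = \max(10^{-8}, (s^2 - \bar m)/\bar m^2)$ is pooled
  within condition. With four or five replicates this estimate has
  only a handful of degrees of freedom, and plugging it into a normal
  Wald statistic is anticonservative (the statistic behaves like a
  t with few degrees of freedom). We therefore share information
  across genes by default: raw estimates are replaced by their mean
  within 20 quantile bins of the log mean (`trend = TRUE`). This is
  the same reasoning that leads established RNA-seq testers to shrink
  dispersions toward a trend, implemented here in its simplest
  testable form. The calibration suite verifies that the resulting
  type-I error on null NB data (2,000 genes, 5 vs 5, $\alpha = 0.1$,
  ten seeds) stays inside [0.03, 0.07] at nominal 0.05; with
  `trend = FALSE` it does not. The bin mean (not median) is used: the
  method-of-moments estimate is right-skewed, and the mean's mild
  upward weighting offsets the optimism of the plug-in statistic.
* **No shrinkage of fold changes**, no outlier handling, no
  independent filtering: deliberately out of scope, so headline DEG
  counts from a full DESeq2 analysis of the real data are not
  reproduction targets.

# Co-expression modules

Genes with fewer than 10 counts in more than 90% of samples are
removed (`filterLowCounts`, applied to raw counts before
transformation), expression is taken as
$\log_2(\text{count}/s_j + 1)$ — a simple variance-stabilizing
stand-in for the vst, pluggable if an exact vst is wanted — and the
unsigned network is built from $s_{ij} = |\mathrm{cor}(x_i, x_j)|$
(Pearson; unsigned so that strong negative co-regulation counts as
co-expression) with adjacency $a_{ij} = s_{ij}^\beta$, $\beta = 9$ by
default as appropriate for small sample sizes. The topological
overlap is

$$\omega_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
  {\min(k_i,k_j) + 1 - a_{ij}},$$

and modules come from average-linkage clustering of $1-\omega$.

**Adaptive branch decomposition.** At $\beta = 9$ the TOM
dissimilarities compress toward 1, so a cut at a fixed absolute
height is meaningless; all heights here are fractions of the span
between the lowest and highest merge. Candidate branches are the
clusters at 0.95 of the span. Each branch is then scanned downward to
a floor set by `deep_split` (0 → 0.95, 1 → 0.90, 2 → 0.85,
3 → 0.80, 4 → 0.75) and split at the first height where it separates
into at least two sub-branches of `min_cluster_size` (default 100)
genes, recursively — deeper splits scan further and decompose more.
Sub-branches below the size floor attach to the resulting module
whose eigengene (first principal component of the standardized
submatrix, oriented to correlate positively with its members, unit
norm) correlates with theirs above `rescue_cor = 0.5`; the candidate
is fixed by the dendrogram, not chosen as a maximum over all modules,
which avoids selection-biased accretion of noise branches. Finally
genes whose correlation with their own module eigengene (kME) falls
below `kme_min = 0.5` are released to label 0. The PAM-like
reassignment stage of the original hybrid tree-cut algorithm is
intentionally omitted. Modules whose eigengenes correlate above
`merge_cor = 0.85` are merged iteratively (`mergeSimilarModules`);
the merge threshold is our choice, as is `z_threshold` below — both
are exposed.

**Stage specificity.** Each eigengene is z-scored across samples; a
module is specific to a condition when its mean z reaches
`z_threshold = 0.8` there and stays below it everywhere else. A
two-peak profile is deliberately "none": specificity means one stage.

# Ortholog resolution

Candidate pairs (from an annotation export with gene-order
conservation, whole-genome-alignment coverage, and reciprocal percent
identities) are filtered to those flagged high confidence *or* with
similar names. Name similarity — a convention rather than a definition — is
operationalized as case-insensitive equality, or equality
after stripping one trailing zebrafish paralog suffix (a single
`a`/`b`, or `.N`) from the source symbol; a strict-equality rule is
available (`name_rule = "strict"`).

Each source gene then receives one target: among name-matched
candidates when any exist (a name match outranks any metric),
otherwise among all, by the lexicographic maximum of (GOC, WGA
coverage, %id source→target, %id target→source). Missing metrics rank
lowest (annotation exports contain blanks); remaining ties break on
ascending target id so resolution is deterministic. Finally, targets
claimed by several sources keep only their high-confidence claims;
sources orphaned by this reduction are dropped with a message, and
targets still claimed by two or more sources are flagged — reports
append an asterisk to them. The resolver is checked against an
exhaustive brute-force implementation of the three rules on random
tables.

# Cross-species comparison

DEG tables are translated into target-id space; when two source genes
map to one target with conflicting directions, the larger
$|\log_2\!\mathrm{FC}|$ wins and the row is flagged. Intersections are
direction-stratified: shared means present in both sets in either
direction, then split into same-direction and opposite (matching the
convention "N shared, of which M in the same direction"). UpSet
regions count genes belonging with a given direction to exactly one
subset of the sets; regions partition each direction's union. The
union fold-change matrix takes genes DE in at least one stage and
present in at least one cancer set, masking cells with FDR above
`mask_fdr = 0.1` or fold change below 1.5 in both directions — the
masking FDR is looser than the DE call's 0.05 by design — "weakly
regulated" is a broader notion than a confident DE call — and is
exposed as a parameter.

Stage-to-cancer similarity is quantified as the **signed Jaccard**
index, $(\text{same} - \text{opposite}) / |\text{union}|$: 1 for
identical direction-tagged sets, negative for anti-concordant ones, 0
for disjoint ones. Eyeballing shared counts and heatmaps is how such
rankings are usually made; the signed Jaccard makes the ranking
explicit, and the raw counts are always reported alongside so a
count-based reading remains possible.

Percent-unique values are $100 \times \text{exclusive}/\text{total}$
per set, rounded half-up (a zero total is not applicable, NA).

# Enrichment

The EASE score is the jackknifed one-tailed Fisher test: the
hypergeometric upper tail with the query hit count reduced by one,
so $k \le 1$ can never be significant and EASE ≥ Fisher everywhere.
BH correction is applied within each term category (BP/MF/CC/pathway
lists are reported separately). The default universe is the set of
genes tested for differential expression in the relevant contrast.
Term collections come from user-supplied GMT files; no live
annotation service is queried.

# The synthetic-data generator

`simulateCounts` emulates the study design: groups control:5, dpl1:4,
dpl3:4, dpl14:5 (four or five replicates per group totalling 18; the
exact split is an assumption and is configurable);
log-normal baseline means (meanlog 4, sdlog 1.5 — a realistic bulk
RNA-seq mean spread); NB dispersion $\alpha = 0.1$; per-sample size
factors log-uniform in [0.5, 2] so normalization is genuinely
exercised; 5% of genes planted DE per stage at $|\log_2\!\mathrm{FC}|
= 2$ with 60% Up (differential expression in the study skews Up).

Planted modules are driven by one latent factor per sample and
module: $\text{mean}_{gj} = \mu_g \exp(a f_j - a^2/2)$ with equal
loadings. The factor is standardized to unit sample variance so the
realized signal-to-noise ratio does not fluctuate with the draw, and
the loading is set from the average log-scale counting-noise variance
$\overline{1/\mu + \alpha}$ to hit the target pairwise correlation
(default 0.7). Module baselines are drawn tighter and higher
(meanlog 5, sdlog 0.5) so counting noise does not dominate. The
factor mean is shifted by `module_peak_shift = 3` standard deviations
in the module's peak stage: a factor-level calculation shows that at
shift 2 a four-replicate stage fails the z ≥ 0.8 single-peak call in
roughly a fifth of draws — such modules would not be "stage-specific"
in any usable sense — while at shift 3 the miscall rate is a few per
thousand. Two caveats the tests make explicit: (i) the planted
correlation is verified on expression normalized by the generator's
own size factors — in dense compositions where most genes belong to
modules (as in the recovery benchmark: 360 of 660 genes),
median-of-ratios normalization absorbs part of the shared factor and
attenuates the realized correlation; (ii) the generator has no batch
effects, GC/length bias, outlier samples, or correlated noise beyond
the planted factors, so passing tests demonstrate correctness of the
machinery, not robustness to everything real data contains.

`simulateOrthology` plants five candidate classes (unique
high-confidence; name-matched with a better-scoring decoy; one-to-many
with a metric-dominant winner; many-to-one pairs, both high
confidence; low-confidence-only, unresolvable) with metrics drawn so
the intended winner strictly dominates. `simulateAnnotation` plants
enriched terms inside uniform background terms.

The end-to-end pipeline (`runPipeline`) additionally plants the
cross-species gradient: the two simulated cohorts re-use 60% / 30% /
10% of the dpl1 / dpl3 / dpl14 planted DE genes (same direction,
through the orthology truth map) plus cohort-private DE genes, so the
expected similarity ordering is dpl1 > dpl3 > dpl14 — the structure
the pipeline is supposed to detect.

# Problem sizes and runtime

Defaults are chosen to keep a complete run interactive on one CPU:
6,000 genes, with the network stage restricted to the 2,000 most
variable filtered genes (TOM is cubic in gene count). The module
recovery benchmark uses three blocks of 120 genes plus 300 noise
genes at n = 18; DE calibration uses 2,000 genes across ten seeds.
A full `runPipeline` at defaults completes in well under five
minutes; every stage is deterministic given the master seed, from
which all stage seeds are derived.

# Known limitations

* The variance-stabilizing transform is a log stand-in, not the exact
  vst; module boundaries can differ from a WGCNA run on vst counts.
* The dynamic tree cut is a span-relative, scan-based stand-in for the
  original hybrid algorithm (no PAM stage); `deep_split` maps to a
  scan floor rather than the original heuristic's parameters.
* Two-group contrasts only; no general design matrices, no shrinkage
  estimators, no outlier handling.
* Headline counts from the real datasets (for example total DEGs per
  stage) are not reproducible here by design; the worked-example
  quantities recomputed from reference per-stage counts (the
  percent-unique values and the reciprocal down-cutoff) are.
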