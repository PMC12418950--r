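---
title: "Models and methods behind scMethTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scMethTx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scMethTx)
library(data.table)
```

## The problem

Oocytes matured in vitro (IVM) tend to reach the blastocyst stage less often
than oocytes matured in vivo, and the molecular basis of that gap is
studied by profiling the same cells with single-cell RNA-seq and single-cell
bisulfite sequencing (scBS-seq). The data are characteristic: two small
groups of cells (around 16 per group), very sparse CpG coverage (0.5-3x, with
roughly a third of CpG sites observed per cell), global CpG methylation near
47%, and polyadenylated transcript counts that follow a negative-binomial
law. scMethTx implements the complete desk-side analysis for this design —
QC gating of both omics, region-level methylation quantification, a
filter-cascade differential-methylation caller, a negative-binomial
differential-expression test, and joint factorization plus
methylation-expression correlation — together with a seeded generator that
produces data with exactly this structure, so every stage is testable
without any sequencing data.

## Coordinate conventions

All internal intervals are 0-based half-open; a CpG belongs to a region when
its cytosine position lies in `[start, end)`. Bismark-style coverage files
are 1-based and are converted at the I/O boundary only, as are gene tables.
The percent-methylation column of coverage files is never trusted: counts
are authoritative, and a stored percentage disagreeing with the counts by
more than half a point raises a warning. CpG dyads can optionally be
collapsed (`merge_symmetric_cpg`), summing the plus- and minus-strand calls
of one palindromic site; at sub-1x coverage this raises effective depth and
is the default in the pipeline's intended use.

## Quality control

RNA cells are kept when they satisfy, conjunctively: at least 25 000 reads
and 5000 detected genes, at most 7500 detected genes and 2 000 000 total
molecules, and at most 5% mitochondrial counts. Lower bounds are inclusive,
upper bounds inclusive. The grammatically natural reading of these rules is
the conventional one — the printed numbers are upper bounds for
`nFeature`/`nCount`/percent-mito and lower bounds for reads/genes; any other
reading discards essentially every cell. Bisulfite cells are kept when they
cover at least 500 000 CpG sites and their global methylation lies strictly
between 30% and 70% (a cell at exactly 30% is discarded). The read/gene/CpG
lower bounds are full-genome numbers: on reduced synthetic genomes they are
passed scaled to the simulated library size (the packaged demo uses 100
reads / 15 genes / 500 CpGs against per-cell libraries of about 3000
molecules and 7000 covered CpGs); the mitochondrial and methylation-window
gates are scale-free and stay at their defaults everywhere. A diagnostic for
atypical TSS-proximal methylation (|z| > 3 across cells) is reported but
never excludes a cell, because no operational exclusion rule exists for it.

## Region-level methylation

Regions come in seven classes: CpG islands, promoters (TSS ± 2 kb,
strand-independent), gene bodies, transposons, 1-kb genome windows,
variably methylated regions (VMRs), and imprinted germline DMRs. Within a
(region, cell) pair, only CpG sites with at least `min_cov_per_cpg` reads
(default 5) contribute; the default estimator is the read-weighted pooled
ratio `sum(n_meth) / sum(reads)`, because per-CpG fractions at 1-5 reads are
too unstable to average. The unweighted per-CpG mean is available
(`pooling = "cpg_mean"`) since either weighting is defensible.

VMR detection is a transparent variance-rank procedure: windows observed in
at least half the cells are ranked by across-cell variance of their
methylation fraction, the top 2% (configurable) are selected, and runs of
adjacent selected windows are merged into variable-length VMRs ranked by
their maximum window variance. This is a deliberate, documented surrogate
for unpublished scanning internals of the tools used in the field; its
parameters are exposed and its behaviour is pinned by closed-form variance
oracles in the tests.

## The differential-methylation caller

The caller applies a three-rule cascade and then a per-region two-sample
test:

1. per-site coverage of at least five reads (applied during aggregation);
2. at least half the cells of *each* group must have reads in the region
   (`ceil(0.5 x group size)`, inclusive);
3. the mean over contributing cells of the region's read total must be
   strictly greater than 10 in each group.

Rule 3's "average reads" is read as the mean per-cell region read total; a
per-CpG-coverage alternative is available (`rule3_metric = "per_cpg"`) since
either reading of "average reads of cytosines" is defensible. The test is
R's `t.test` with default parameters — which is the unequal-variance Welch
test, even though this procedure is usually described as a Student t-test;
both variants are implemented and the pooled-variance form is one switch
away. A region is a DMR when `p < 0.05` (uncorrected by design; BH correction is
available but off by default to preserve comparability) and the absolute
group difference in methylation fraction exceeds 0.1 — "FC > 0.1 (10%)" is
interpreted as 10 percentage points, not a ratio, as the parenthetical
percentage indicates. Group levels above 75% are labelled hypermethylated
and below 25% hypomethylated, per group, so a region can be "hypo in group
1" while intermediate in group 2; summary percentages (e.g. 42 of 52
labelled CGI DMRs = 81% hypomethylated) use half-up integer rounding.
Regions passing the cascade but with fewer than two covered cells in a
group are reported as untested rather than silently dropped.

## Differential expression

The DE engine is a transparent negative-binomial Wald test built from
scratch rather than a clone of any published package: median-of-ratios size
factors; per-gene method-of-moments dispersion from the pooled within-group
variance of normalized counts, shrunk (weight 0.7) toward a binned-median
mean-dispersion trend; `log2fc = log2((m1 + 0.5) / (m2 + 0.5))` with a 0.5
pseudocount for stability at single-cell sparsity, group 2 (the in-vivo-like
group) being the reference; and a Wald statistic dividing the fold change by
a delta-method standard error from the NB variance `mu + alpha mu^2`.
P-values use a t reference with `n1 + n2 - 2` degrees of freedom rather
than a normal: at 16 + 16 cells the moment estimate of the dispersion is
noisy, and the heavier-tailed reference is what keeps the null p-value
distribution uniform (the test suite checks this with a Kolmogorov-Smirnov
test over 2000 null genes, and checks the near-Poisson limit against a
Poisson GLM). DEGs require BH-adjusted FDR < 0.05 and |log2FC| >= 2; a
looser 1.5 threshold also circulates for this design, so the cutoff is
configurable. Genes expressed in fewer than 3 cells are excluded from
testing (a minimal prefilter the moment estimator needs to exist).
Highly variable genes (top 2000 by trend-standardized variance of
log1p-normalized counts, deterministic tie-break by gene id) feed only the
PCA/embedding, never the test.

## Integration

The two omics layers are factorized jointly: minimize
`||X_rna - W_rna H||^2 + lambda ||X_meth - W_meth H||^2` over non-negative
factors by Lee-Seung multiplicative updates, sharing the factors-by-cells
loading matrix `H`. This replaces the published single-cell aggregation
tool's cell-cell-similarity machinery with a plain joint NMF on purpose:
such tools are black boxes, and what matters
downstream — cluster recovery and factor markers — is pinned directly by
tests (adjusted Rand index 1 on well-separated data, monotone objective
descent every iteration). `lambda` (default 1) weights the methylation
layer; `lambda = 0` provably decouples `H` from methylation, with `W_meth`
fitted post hoc. Missing methylation entries are imputed with the region's
cross-cell mean before factorization only; correlation analysis uses
pairwise-complete observations and never imputes. Factor markers are
Wilcoxon assigned-vs-rest contrasts retained at `p < 0.05` and natural-log
fold change > 0.25 ("FC > 0.25" is taken as a natural-log fold change, the
convention of the single-cell toolkit family this emulates).

Methylation-expression correlation considers (locus, gene) pairs on the same
chromosome with locus midpoint within 500 kb of the TSS, over promoter, CGI
and VMR loci. Within each group, Pearson correlation over cells with both
values present (at least 5); a pair is reported for a group when
`|r| >= 0.5`, the between-group difference of correlations exceeds 0.1, and
`|r| > 0.2` (retained as a guard although implied by the first clause —
the three thresholds are not mutually unambiguous, so each clause is
independently switchable). Correlations are computed within-group, not
across all cells, because the quantity of interest is the per-group count
of positive and negative regulatory relationships. When the other group's correlation cannot be computed it is treated
as zero in the difference clause.

## The synthetic-data generator

The generator is first-class, tested code that defines the package's study
conditions: two groups of 16 cells; a small multi-chromosome genome with
non-overlapping gene bodies, symmetric promoters, CGIs (half on promoters,
half intergenic), transposons and imprinted gDMRs; global methylation
centred on 0.47; capture of ~30% of CpG sites per cell with 1 + Poisson
read depth (`coverage_mean` 3 by default, matching 0.5-3x data);
beta-binomial methylation noise (`rho = 0.2`) drawn once per cell per 1-kb
latent unit so neighbouring CpGs are correlated within a cell, which is
what makes region fractions t-testable; NB counts (dispersion 0.3) around
log-normal gene means with log-normal library sizes; and 13 mitochondrial
genes — the number of protein-coding genes on the mitochondrial genome —
holding 2% of counts in expectation, so healthy cells sit well below the 5%
QC gate. Imprinted gDMRs are simulated at 0.95/0.05 methylation identically
in both groups, encoding the expectation that genomic imprinting is
maintained regardless of maturation condition; planted DMRs never target a
region an imprinted override would rewrite.

Planted effects are signed and alternating: DMRs shift group 1 by
±`dmr_delta`/2 against group 2 around a mid-range base level (clipped to
[0.02, 0.98] with a warning); DEGs multiply the group-1 mean by
`2^(± deg_log2fc)`; coupled promoter-gene pairs make the group-1 expression
of a gene decrease log-linearly in that cell's latent promoter methylation
while group 2 stays uncoupled. Effect sizes are configuration, not
estimates of any real effect-size distribution, and the
recovery analyses use deliberately well-separated settings (delta 0.4,
|log2FC| 2.5, coupling slope 6 at coverage 20) because they test that the
callers find what is plainly there, not the detection frontier. QC-outlier
cells (high-mito, tiny-library, 25%-methylation, low-CpG-capture) can be
appended to group 1 with names recorded in the truth tables.

What the generator does not emulate: fragment-level coverage
autocorrelation (capture is i.i.d. per CpG beyond the shared latent unit),
bisulfite conversion failure, doublets, batch effects, and any real genome
sequence. Passing recovery tests therefore demonstrates correctness of the
statistical machinery under the stated model, not performance on real
libraries.

## Determinism and problem sizes

Every stage derives its RNG stream from a global seed via a stable string
hash of the stage name, so adding or removing one stage never perturbs
another, and rerunning a configuration reproduces byte-identical outputs
(verified by md5 in the manifest). The packaged demo uses a 0.8 Mb genome
with 40 genes and completes in well under a minute; the calibration
analyses use 2500 one-kb windows (a 2.5 Mb genome) for the
differential-methylation null and 2000 genes for the expression null —
sizes chosen to give binomially tight estimates of a 5% false-positive rate
while keeping the whole suite interactive.

## Known limitations

The DM test operates on per-cell region fractions, not on read counts; a
beta-binomial regression would use the counts more efficiently at very low
coverage but would depart from the simple `t.test`-based procedure this
package reproduces. The NB Wald test does not share information across
genes beyond the dispersion trend, so it is less powerful than
empirical-Bayes machinery at extreme sparsity. The NMF replaces, rather
than reproduces, the published integration tool. VMR calling is a variance
ranking, not a likelihood scan. Headline DMR/DEG counts from real
sequencing libraries cannot be reproduced at desk scale, and the package
does not attempt to.
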