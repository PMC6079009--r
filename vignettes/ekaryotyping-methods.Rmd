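---
title: "Expression-based karyotyping and tumor cohort statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-based karyotyping and tumor cohort statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ekaryotypeR)
```

# The problem

A chromosomal gain or loss changes the DNA dose of every gene it covers, and
bulk RNA-seq inherits that dose as a broad, coherent shift in expression.
E-karyotyping exploits this to read copy-number alterations (CNAs) directly
from an expression matrix — useful when characterizing tumor models (for
example, mammary tumors of conditional knockout mice) for which no DNA-level
copy-number assay was run. This vignette documents the model, the parameter
choices, what the synthetic cohorts do and do not emulate, and the numerical
conventions, in enough detail to audit or extend the package.

# E-karyotyping

## From expression to deviation tracks

Inputs are log2-scale, library-normalized expression values (FPKM or
equivalent; the package does not normalize). Preprocessing is:

1. **Expression filter** (`filter_policy("ekaryo")`): a gene is dropped iff
   its log2 value is below 1 in *all* samples; surviving values below 1 are
   floored to 1. The flooring is applied on the log2 scale: the filter is
   defined after log transformation, and flooring before the transform would
   make the threshold and floor inconsistent units. A second dialect
   (`"gemm"`, threshold 5.5 in strictly more than 20% of samples, floor 5)
   matches the harsher filter conventionally used when pooling microarray
   panels of engineered mouse mammary tumor models; the strictly-greater
   reading means a gene low in exactly 20% of samples survives.
2. **Comparative values** (`comparative_values()`): per gene, subtract the
   median over the normal reference panel (median rather than mean so a
   single outlying normal cannot shift a gene's baseline; the mean is
   available, and is also what heatmap scaling uses). With an even reference
   count the median is the usual midpoint, so the "reference centers at
   zero" property is exact only for odd panels.
3. **Genome ordering** (`order_by_genome()`): sort by (chromosome, start),
   breaking exact position ties by gene id so runs are reproducible. Genes
   missing from the annotation are dropped and reported, never silently.

## Winsorization

Before segmentation each sample's whole-genome track is winsorized at
quantile *q* (default 0.001): the `k = floor(q·n)` most extreme values on
each side are clamped to the (k+1)-th order statistic from that side. This
is the classic order-statistic convention (the one behind the winsorized
mean) rather than an interpolated-quantile cutoff; it was chosen because it
is idempotent — winsorizing a winsorized track is a no-op — which an
interpolated cutoff is not, and idempotence is the natural contract for an
outlier clamp. Winsorization is per sample, not per chromosome: outliers are
a property of a library, and per-chromosome quantiles on ~300-gene
chromosomes would be too noisy to estimate at q = 0.001.

## Exact penalized piecewise-constant fit

A chromosome's track $c_1..c_n$ is segmented by minimizing

$$\sum_{\text{seg}} \sum_{i \in \text{seg}} (c_i - \bar c_{\text{seg}})^2
  + \lambda \,(\#\text{segments} - 1)$$

over all $2^{n-1}$ breakpoint sets. `pcf_segment()` solves this exactly by
dynamic programming in $O(n^2)$ using prefix sums; the test suite checks the
optimum against literal exhaustive enumeration on short tracks. Among
equal-cost solutions (within $10^{-9}$) the program prefers fewer segments,
then earlier segment starts. Breakpoints never cross chromosome boundaries,
and degenerate inputs (empty tracks, NaN) fail loudly.

**What the penalty buys, and its scale.** Splitting one block into two whose
means differ by $\delta$ reduces the squared error by
$\frac{n_1 n_2}{n_1+n_2}\,\delta^2$, so a breakpoint is introduced only when
the harmonic mean of the flanking block sizes exceeds about
$2\lambda/\delta^2$ — 150 genes for $\lambda = 12$ and a single-copy-scale
$\delta = 0.4$. Two consequences:

* Whole-chromosome and arm-scale events, which need no interior breakpoints
  (the segment mean alone carries them past the calling rules), are the
  method's natural targets, and are what the recovery experiments plant.
* Focal events of a few dozen genes cannot be split out at the raw-scale
  default penalty regardless of noise level. For them
  `ekaryotype(..., normalize_noise = TRUE)` rescales each sample's track by
  a robust noise estimate (median absolute successive difference /
  $\sqrt2$, floored at $10^{-3}$ to survive noise-free tracks) before
  segmentation, making the penalty noise-relative; calls are always made on
  raw log2 means. The raw scale remains the default because the headline
  parameter set is defined on raw winsorized log2 data.

## Calling gains and losses

A fitted segment is called `gain`/`loss` only if all three hold
(`pcf_params()` defaults):

* $|\bar c| \ge 0.25$ log2 units (**least allowed deviation** — roughly half
  the $\log_2(1/2) = -1$ of a clonal one-copy loss, leaving room for normal
  cell admixture and dosage compensation);
* the segment spans ≥ 30 genes (**least allowed aberration size** — broad
  events only, which is also where the expression-dose signal is coherent);
* a two-sided one-sample t-test of the member values against 0 has
  p ≤ 0.01 (**threshold**). The threshold is read as the significance level
  of a per-segment location test because that is the only reading that makes
  the parameter operative alongside the two hard rules. Degenerate segments
  are resolved deterministically: one gene is never significant; a constant
  segment is p = 0 unless it sits exactly at zero (this makes zero-noise
  simulations behave like their infinite-precision limit).

Adjacent segments with the same call are merged with a pooled mean, so the
output per sample × chromosome is a tiling alternating between calls.
Segment bp coordinates are start of first gene to start of last gene + 1
(genes are point-located; transcript lengths are not modeled). `write_seg()`
/ `write_bed()` emit IGV-compatible tables; `moving_average_tracks()`
produces the valid-convention smoothed tracks (default window 50 genes — a
compromise between locus resolution and the ~0.3 log2 noise of per-gene
comparative values; the window is configurable) used for locus-level plots.

# Molecular subtyping

`assign_subtype()` computes the Spearman correlation (Pearson on mid-ranks;
mid-ranks handle ties, and rank correlation makes calls invariant to any
monotone rescaling of a sample) between a sample and each centroid over
their shared genes, requiring at least 3. The top subtype is assigned unless
the top two correlations differ by less than `mixed_margin`, in which case
the call is `mixed`. The margin defaults to 0.05: "similar correlations" is
inherently a judgment call, and 0.05 is small enough that clean planted
panels are never flagged yet reliably catches a sample constructed as the
average of two centroids. Margins below $10^{-12}$ are treated as exact ties
(floating-point summation order can perturb a mathematically exact tie by an
ulp). Centroids are an input file, not shipped: published centroid tables
have their own licenses and versions, and the classifier is agnostic to
which is used. The tests use a synthetic 3-subtype × 30-gene table.

# EMT scoring and clustering

`emt_score()` sums comparative values over the gene-set members present in
the (already filtered) matrix — "expressed" is thus bound to whichever
filter policy produced the matrix. A sum, not a mean: panels are compared on
a fixed shared gene list, where the sum is the mean times a constant, and
the sum convention matches how such scores are usually reported. Symbol
matching is case-insensitive with an optional explicit map, because EMT
sets are human (upper-case) while mouse symbols are capitalized; the
package deliberately does not guess orthology beyond that.

`hierarchical_cluster()` is agglomerative clustering of samples with
Euclidean distance and complete linkage via `stats::hclust` (the tests
verify its merge heights against a naive quadratic agglomeration written
independently); `scale_for_heatmap()` is per-gene mean centering; dendrogram
export is Newick via `ape`.

# Cohort statistics

`build_contingency()` cross-counts two genes' perturbation status under
either definition — `homdel` (status `deleted` or `both`) for strict
deletion co-occurrence, `mut_or_del` (any non-WT) for grouping — and
`fisher_exact_two_sided()` computes the probability-mass two-sided p: the
sum of hypergeometric probabilities of all tables (margins fixed) no more
probable than the observed one, with a $1+10^{-7}$ relative buffer for
floating ties. Two-sided Fisher definitions genuinely differ between
packages; the probability-mass rule is stated explicitly and checked against
both an independent log-binomial enumeration and `stats::fisher.test`. The
reported odds ratio is the sample cross-product $ad/bc$ (with Inf/0/NaN
conventions for empty cells), not the conditional MLE.

Kaplan–Meier curves (`km_curve()`) and the k-group log-rank test
(`logrank_test()`) wrap the `survival` package (product-limit estimator;
ties between events and censorings at one time are handled events-first, the
standard convention). The modules are endpoint-agnostic: they take (time,
event) as given and never decide what the endpoint means.

# The synthetic cohorts

The generators produce inputs with exactly the statistical structure each
stage assumes, so every guarantee is testable without downloads:

* **Expression** (`simulate_expression_cohort()`): per-gene baselines drawn
  once from Uniform[2, 10] log2 units (the bulk of a filtered RNA-seq
  expression distribution), with 5% of genes placed below the expression
  filter so filtering has work to do; planted events add a constant log2
  shift over a contiguous within-chromosome gene range; noise is i.i.d.
  Gaussian on the log2 scale (the pipeline lives entirely on log2 values,
  and additive Gaussian noise there is the simplest model consistent with
  floored-log preprocessing), default sd 0.3. The single-copy loss default
  of −0.4 log2 is a package choice, not a measured value: clonal one-copy
  loss would give −1, and −0.4 reflects substantial normal-cell admixture.
* **Event truth** is emitted in the same half-open gene-index convention as
  segment calls, so recovery scoring (`score_event_recovery()`) is a set
  comparison with an overlap fraction (default 0.5).
* **Subtype panels**: centroid column + Gaussian noise.
* **Perturbation tables**: the Plackett joint Bernoulli — the unique 2×2
  distribution with the requested marginals and odds ratio (quadratic root
  in the Fréchet interval) — then status labels drawn among
  mutated/deleted/both for perturbed samples.
* **Survival**: exponential event times per group with independent
  exponential censoring.

All generators take a seed, are bit-reproducible, and restore the caller's
RNG state. What they do *not* emulate: gene-length or GC biases, count
noise (over-dispersion at low expression), correlated co-expression
structure, subclonal or partially clonal events, batch-by-condition
confounding, or informative censoring. Passing recovery tests therefore
demonstrate the inference machinery is correct under its own model — not
that real cohorts meet that model.

# Experiment sizes

The packaged experiments are deliberately desk-scale, chosen so the whole
suite runs in well under a minute per component: recovery cohorts use 5
chromosomes × 300 genes with 3 normal and 4 tumor samples and a
whole-chromosome loss planted in 3 of the 4 tumors (100 seeds);
segmentation is verified against exhaustive enumeration on 500 tracks of
length ≤ 12 (beyond which $2^{n-1}$ enumeration explodes); Fisher p is
checked on all 135,750 tables with n ≤ 40; log-rank calibration uses 1,000
null replicates of two 100-subject groups. Batch handling is per-batch mean
centering that preserves gene-wise grand means — it removes additive batch
offsets only, and is not an empirical-Bayes batch correction.

# Known limitations

* Expression dose is an indirect CNA readout: trans-acting regulation,
  tumor-normal composition shifts, and chromosome-scale transcriptional
  programs can mimic or mask dosage. Calls are *expression-consistent*
  copy-number states, not DNA measurements.
* The raw-scale penalty limits detection to broad events (see above);
  `normalize_noise` is provided but changes the meaning of the penalty.
* No allele-specific or integer copy-number estimation, no GC correction.
* Nearest-centroid calls depend on the centroid table's platform and gene
  coverage; with few shared genes the Spearman estimate is coarse (the
  hard floor is 3 genes, but tens are needed for stable calls).
* The EMT score inherits the comparative values' reference panel: it ranks
  groups within a jointly processed cohort and is not comparable across
  independently filtered datasets.
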