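# ekaryotypeR

Expression-based karyotyping (e-karyotyping) and the cohort statistics that
typically accompany it in tumor-model studies: copy-number inference from
bulk RNA-seq, nearest-centroid molecular subtyping, EMT signature scoring,
perturbation co-occurrence testing, and Kaplan–Meier survival comparison.
The package targets researchers characterizing tumor models (e.g. engineered
mouse mammary tumors) from expression data alone, when no DNA-level
copy-number assay is available.

## The method

**E-karyotyping.** Chromosomal gains and losses leave a dose footprint in
expression: genes inside a lost segment are transcribed from one copy
instead of two. The pipeline works on log2 expression values \(x_{gs}\):

1. drop non-expressed genes (log2 value < 1 in all samples) and floor the
   rest at 1;
2. form *comparative values* \(c_{gs} = x_{gs} - \mathrm{median}_{r \in
   \text{normals}}\, x_{gr}\);
3. order genes by chromosomal position, winsorize each sample's track at
   quantile \(q\);
4. per chromosome, fit a piecewise-constant signal by minimizing
   \[\sum_{\text{seg}} \sum_{i \in \text{seg}} (c_i - \bar c_{\text{seg}})^2
     + \lambda\,(\#\text{segments} - 1),\]
   solved *exactly* by an \(O(n^2)\) dynamic program over breakpoints;
5. call a segment a gain/loss when \(|\bar c_{\text{seg}}| \ge 0.25\) log2
   units, it spans ≥ 30 genes, and a one-sample t-test against 0 is
   significant at 0.01.

Defaults: deviation 0.25, size 30 genes, winsorize q = 0.001, penalty
λ = 12, test threshold 0.01.

**Subtyping.** Each sample is correlated (Spearman, mid-ranks) against every
column of a supplied centroid table (e.g. the PAM50 intrinsic subtypes) over
their shared genes; the best-correlated subtype is assigned, and a sample
whose top two correlations are within a margin (default 0.05) is called
`mixed`.

**EMT score.** Per sample, the sum of comparative values over the expressed
members of an epithelial–mesenchymal-transition gene set; group means rank
tumor models by mesenchymal character.

**Cohort statistics.** Two-gene perturbation tables are cross-tabulated and
tested for co-occurrence with a two-sided Fisher's exact test
(probability-mass rule); survival is compared across the four joint
perturbation groups with Kaplan–Meier curves and the k-group log-rank test.

A synthetic-cohort module generates every input — genome annotations,
expression with planted copy-number events, centroid-correlated subtype
panels, association-controlled perturbation tables, grouped exponential
survival — so the full pipeline is testable without any external download.

## Worked example

A desk-scale cohort of 3 normal and 4 tumor samples over 5 chromosomes ×
300 genes, with a whole-chromosome single-copy loss (−0.4 log2) planted on
chr2 in tumors T1–T3:

```r
library(ekaryotypeR)

ann   <- simulate_annotation(n_chromosomes = 5, genes_per_chromosome = 300, seed = 11)
truth <- planted_events(c("T1", "T2", "T3"), "chr2", 1, 300, -0.4)
sim   <- simulate_expression_cohort(ann, n_normal = 3, n_tumor = 4,
                                    events = truth, noise_sd = 0.3, seed = 11)

expr <- apply_filter_policy(sim$expression, filter_policy("ekaryo"))
cmp  <- comparative_values(expr, names(sim$condition)[sim$condition == "normal"])
segs <- ekaryotype(cmp, sim$annotation)
subset(segs, call != "neutral")
#>  sample_id chromosome start_gene_index end_gene_index start_bp   end_bp n_genes  mean_log2 call
#>         T1       chr2                1            289        0 30334571     288 -0.3731678 loss
#>         T2       chr2                1            289        0 30334571     288 -0.3965539 loss
#>         T3       chr2                1            289        0 30334571     288 -0.3914340 loss
```

Exactly the three planted tumors are called, chromosome-wide (288 of the 300
genes survive the expression filter), with fitted means near the planted
−0.4; `score_event_recovery(sim$truth, segs)` confirms TP = 3, FP = 0,
FN = 0 (F1 = 1.00). T4 and the normals show no aberration.

Co-occurrence on a simulated 2,509-sample cohort with marginal perturbation
rates 35% / 5% and odds ratio 10:

```r
tab <- simulate_perturbation_table(2509, p_geneA = 0.35, p_geneB = 0.05,
                                   odds_ratio = 10, seed = 11)
ct  <- build_contingency(tab, "geneA", "geneB", definition = "mut_or_del")
fisher_exact_two_sided(ct)
#>            geneB
#> geneA       perturbed   WT
#>   perturbed        98  797
#>   WT               31 1583
#> Fisher two-sided p = 1.09e-21, OR = 6.28
```

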