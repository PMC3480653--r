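# t1dnet

Immune gene expression **relationship profiles** across stages of type 1
diabetes (T1D), as a tested, reusable R pipeline.

Instead of asking whether individual immune genes are up- or down-regulated,
this package analyzes how the *relationships* among thirteen immune genes —
T-cell markers (CD3G, CTLA4), B-cell markers (CD19, CD20), myeloid markers
(CD11b, TLR9, ARG1) and six S100-family genes — change between healthy
controls (HT) and at-risk (AT), new-onset (NO) and long-term (LT) T1D
patients. It is intended for computational immunologists working with
qRT-PCR-style relative expression panels, and ships a synthetic cohort
generator so every stage is reproducible without patient data.

## What it computes

1. **Ratio profiles** — per-sample ratios of a regulatory gene to a lineage
   marker (e.g. CTLA4/CD3G), summarized per group with rank-based
   comparisons.
2. **Co-expression networks** — per-group Pearson correlations for all 78
   gene pairs, classified as strong (|r| ≥ 0.9) or moderate
   (0.8 ≤ |r| < 0.9); robust-z outlier screening; groups below a minimum
   size are refused rather than estimated unreliably.
3. **Hierarchical clustering** — genes clustered on correlation distances
   (d = 1 − r), with Newick dendrogram export.
4. **Cross-group interaction detection** — the core model. For case group
   vs control group, a logistic regression over all main effects, all 78
   pairwise expression products, and age:

   log P(Y=1)/P(Y=0) = β₀ + Σᵢ Xᵢβᵢ + Σᵢ<ⱼ XᵢXⱼβᵢⱼ + age·βₐ

   fitted by maximizing the elastic-net penalized likelihood
   L(y|β) − λ(1−α)/2·Σβ² − λα·Σ|β| (penalty over the gene coefficients
   only; intercept and age unpenalized) with an in-package coordinate
   descent solver. (α, λ) are selected by leave-one-out cross-validation
   minimizing held-out deviance; sandwich standard errors
   (H+Λ)⁻¹H(H+Λ)⁻¹ give Wald p-values on the active set; model fit is
   checked by Hosmer–Lemeshow and ROC/AUC diagnostics; results are reported
   as a symmetric coefficient table with `*` (p < 0.05) and `**`
   (p < 0.0005) marks.

## A worked example

```r
library(t1dnet)

cfg  <- synthetic_config(seed = 7)   # HT 69 / AT 19 / NO 33 / LT 59
data <- generate_dataset(cfg)

net_ht <- build_network(data, "HT")
net_lt <- build_network(data, "LT")
compare_networks(net_ht, net_lt)
#> network comparison: HT vs LT
#> mean |r|: 0.343 vs 0.394
#> edges gained: 14  lost: 0

ratio_profile(data, "CTLA4", "CD3G")
#> ratio_profile: CTLA4 / CD3G
#>  group  n      mean    median
#>     HT 69 1.1353777 1.0793464
#>     AT 19 1.1404411 1.0307844
#>     NO 33 0.9917978 0.8812203
#>     LT 59 0.9915756 0.9861561

odds_ratio(reported_lt_coefficients()$coefficients["CD3G", "CD20"])
#> [1] 1.233678
```

The comparison shows what the synthetic long-term group is built to emulate:
an overall *strengthened* co-expression network (19 strong edges vs 1 in the
healthy group at seed 7, mean |r| 0.394 vs 0.343) with reduced mean
expression. The last line reproduces the published worked example: a 0.21
interaction coefficient for CD3G × CD20 corresponds to an odds ratio of
1.23 — the odds of long-term T1D membership increase 1.23-fold per onefold
increase in the CD3G·CD20 expression product, all else fixed.

The full pipeline (outliers → networks → dendrograms → interaction model →
diagnostics → ratio profiles, with provenance metadata on every output) runs
via:

```r
report <- run_pipeline(pipeline_config(data, case_group = "LT",
                                       control_group = "HT",
                                       out_prefix = "out/run"))
```

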