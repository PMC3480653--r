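---
title: "Immune gene expression relationship profiles: models and methods"
author: "t1dnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune gene expression relationship profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t1dnet)
```

## The scientific setting

Common type 1 diabetes (T1D) is believed to arise from a breakdown of
immunological tolerance, but the overall state of the immune system in
patients is hard to characterize directly. One tractable system-level readout
is the *relationship* among immune gene expression levels in whole blood:
rather than asking whether individual genes go up or down, one asks whether
the coordination between genes — T-cell markers (CD3G, CTLA4), B-cell markers
(CD19, CD20), myeloid markers (CD11b, TLR9, ARG1), and S100-family genes —
changes across disease stages (healthy HT, at-risk AT, new-onset NO,
long-term LT).

`t1dnet` implements that analysis as a reusable pipeline with four analytic
layers plus a synthetic cohort generator:

1. **Ratio profiles** — a regulatory gene referenced to a lineage marker
   (e.g. CTLA4/CD3G) per sample, compared across groups.
2. **Co-expression networks** — per-group Pearson correlations for all 78
   gene pairs, thresholded into strong (|r| ≥ 0.9) and moderate
   (0.8 ≤ |r| < 0.9) edges.
3. **Hierarchical clustering** — genes clustered on correlation-derived
   distances, exported as dendrograms.
4. **Cross-group interaction model** — an elastic-net penalized logistic
   regression detecting gene–gene interactions that separate a patient group
   from healthy controls, with leave-one-out cross-validation, sandwich
   standard errors, and goodness-of-fit/discrimination diagnostics.

## The interaction model

For a case group (Y = 1) versus control group (Y = 0) the log-odds are
modeled as

$$\log\frac{P(Y=1)}{P(Y=0)} = \beta_0 + \sum_{i=1}^{13} X_i\beta_i
  + \sum_{i=1}^{12}\sum_{j=i+1}^{13} X_iX_j\,\beta_{ij}
  + \mathrm{age}\cdot\beta_a,$$

where $X_i$ is the expression level of gene $i$. With 13 genes this gives
1 + 13 + 78 + 1 = 93 columns for at most ~130 samples, so the coefficients
are determined by maximizing the elastic-net penalized likelihood

$$L(y\mid\beta) - \frac{\lambda(1-\alpha)}{2}\Big(\sum_i\beta_i^2 +
  \sum_{i<j}\beta_{ij}^2\Big) - \lambda\alpha\Big(\sum_i|\beta_i| +
  \sum_{i<j}|\beta_{ij}|\Big),$$

with mixing constant $\alpha \in (0,1]$ and weight $\lambda > 0$. Note the
penalty sums run over the main-effect and interaction coefficients only: the
intercept and age are deliberately unpenalized, exactly as the formula is
written. Age is also left unstandardized; an analyst who wants the
alternative convention (age penalized, as some generic software defaults
would do) can pass a design without the age column and append their own.

### Solver

The maximizer is computed by an in-package IRLS + cyclic coordinate descent
solver (`enet_logistic()`, C++ core): at each outer iteration the binomial
log-likelihood is replaced by its weighted least-squares expansion around the
current linear predictor, and the penalized weighted least squares problem is
solved by coordinate-wise soft-thresholding. Numerical choices:

* fitted probabilities are clamped to $[10^{-8}, 1-10^{-8}]$ and IRLS weights
  floored at $10^{-9}$;
* the outer step is safeguarded by step halving on the exact penalized
  objective, which makes the objective non-decreasing across iterations (a
  property the test suite asserts);
* convergence is declared when the largest coefficient change in an outer
  iteration falls below `tol` (default $10^{-7}$), with a cap of $10^4$
  coordinate sweeps; non-convergence is returned as a flagged fit with a
  warning, never silently;
* penalized coefficients below $10^{-12}$ in magnitude are flushed to exact
  zero so the active set is well defined;
* complete separation shows up as coefficient divergence at small $\lambda$
  and is surfaced by the non-convergence flag rather than masked.

Interaction columns are formed as products of the *raw* expression columns,
and each penalized column is standardized to mean 0, variance 1 after the
products are formed; coefficients are reported back on the original scale.
For $\lambda \ge \lambda_{\max}$ (largest absolute null-model score over
penalized columns divided by $\alpha$) every penalized coefficient is exactly
zero and the intercept equals $\log(n_1/n_0)$ for a design without age — a
closed form the tests exercise.

### Hyperparameter selection

$(\alpha, \lambda)$ are chosen by leave-one-out cross-validation minimizing
the held-out deviance $-2\sum_i \log P(y_i \mid \hat\beta_{-i})$. The
penalized block is re-standardized on every training set. Default grid:
$\alpha \in \{0.1, \dots, 1.0\}$ and 50 log-spaced $\lambda$ values from
$\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$; exact ties are broken
toward larger $\lambda$, then larger $\alpha$ (the sparser model). Grid cells
whose inner fits fail are marked invalid and excluded.

A caveat the package documents deliberately: deviance-minimizing
cross-validation *over-selects under the null*. In simulations with pure
noise outcomes the selected active set is empty in only roughly 60% of
replicates (the reference implementation `cv.glmnet` with `nfolds = n`
behaves the same). Minimum-deviance selection simply does not deliver
null-model selection with high probability; users who need conservative
selection should apply the significance marks, not the active set alone.

### Inference on the active set

Wald inference for the selected coefficients uses the sandwich covariance

$$\widehat{\mathrm{cov}}(\hat\beta_A) = (H + \Lambda)^{-1} H (H + \Lambda)^{-1},$$

restricted to the active columns plus the unpenalized intercept and age,
where $H$ is the observed negative log-likelihood Hessian at the fit and
$\Lambda$ is diagonal with $\lambda(1-\alpha) + \lambda\alpha/|\hat\beta_j|$
for penalized active coefficients (the local quadratic curvature of the
$\ell_1$ term) and 0 for intercept and age. At $\lambda = 0$ this reduces to
the usual inverse observed information. The exact formula used by the
original analysis is cited there but not printed; this form is the package's
own documented choice and is validated against bootstrap standard errors in
the tests (ridge-dominated case, agreement within 25%). Standard errors are
transformed to the original coefficient scale, and two-sided normal p-values
are marked `*` (p < 0.05) and `**` (p < 0.0005) in the reported table —
raw p-values, as in the original reporting, with an optional
Benjamini–Hochberg adjustment flag and a clear caveat that no multiplicity
correction is applied by default.

### Diagnostics

* **Hosmer–Lemeshow**: samples binned by deciles of fitted probability (tied
  probabilities never split), statistic $\sum_g (O_g-E_g)^2 / (E_g(1-E_g/n_g))$
  with $g-2$ degrees of freedom (default $g = 10$); degenerate bins are
  merged with a warning and the degrees of freedom adjusted. Under a
  correctly specified model the resulting p-values are uniform (asserted by a
  Kolmogorov–Smirnov check over 500 simulated fits).
* **ROC/AUC**: the rank (Mann–Whitney) formulation with ties counted half,
  which the tests verify equals the trapezoidal area under the
  threshold-sweep ROC curve on every random instance.

## Networks and clustering

Per-group networks compute all 78 Pearson correlations (`stats::cor` behind
strict input validation: constant vectors raise an error, never a silent 0).
Thresholds are inclusive (≥ 0.9 strong, ≥ 0.8 moderate), matching the
figure-legend convention, and classification depends only on |r|. Pairs are
stored once, lexicographically. Groups smaller than `min_n` (default 20) are
refused with an explicit skip record: the study itself excluded its n = 19
at-risk group as too small to estimate correlations reliably, and kept
n = 33. Whether correlations are computed on raw or log expression values is
not fixed by the original description, so both are supported (`log_transform`
flag) and neither is asserted as the original.

Outlier screening uses a per-group, per-gene robust z-score
$|x - \mathrm{median}| / (1.4826\,\mathrm{MAD})$ with threshold 5. The rule
is intentionally conservative for near-normal data, but on strongly
right-skewed (log-normal-like) raw values it will flag legitimate upper-tail
samples; the `log_transform` flag applies the screen on the log scale
instead. Flagging never removes samples — exclusion is an explicit,
reported step (`drop_samples()`), mirroring the single discarded sample in
the original healthy group.

Clustering converts correlations to distances as $d = 1 - r$ by default
(signed: anti-correlated genes are maximally distant), with $1 - |r|$ as an
option, and applies average linkage (UPGMA) via `stats::hclust`; single and
complete linkage are selectable. Items are sorted lexicographically before
clustering so merge ties resolve deterministically. The original figures do
not state the distance transform or linkage, so no claim is made that these
defaults replicate the published dendrogram topology; the tests validate the
merge sequence against an exhaustive agglomeration oracle instead.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without any
patient data; it emulates the *statistical structure* the analysis assumes,
not the assay.

* **Marginals**: log-normal — relative qRT-PCR quantities are positive and
  right-skewed; the original work states no distribution, so this is a
  stand-in, flagged as such, not an inference about the real data. Default
  log-mean 0 and log-SD 1.0 per gene, i.e. several-fold between-subject
  variation.
* **Correlation structure**: block-structured on the log scale — T-cell and
  B-cell pairs at within-block ρ = 0.92, myeloid and S100 blocks at 0.85,
  cross-block baseline ρ = 0.3.
* **Group sizes**: HT 69, AT 19, NO 33, LT 59 (the study's cohort).
* **Long-term group**: all correlations multiplied by `tighten_factor`
  (default 1.15, clipped at |r| = 0.99 and projected to the nearest
  positive-definite correlation matrix via eigenvalue clipping,
  `Matrix::nearPD`) — emulating the strengthened network observed in
  long-term patients — and log-means shifted by `lt_mean_shift` (default
  −0.3; per-gene shifts supported) for the reduced expression levels.
* **Ages**: truncated normal per group (HT 28 ± 10, AT 16 ± 8, NO 13 ± 6,
  LT 32 ± 12 years, truncated at 0).
* **Labels**: either fixed by design (`group_first`), or drawn from the
  interaction logistic model itself (`label_from_model`) with a planted
  coefficient set, in which case the planted intercept defaults to centering
  the expected linear predictor (balanced classes, computed in closed form
  from log-normal moments). `planted_truth()` returns the exact generative
  parameters for recovery tests.

One PRNG stream per dataset; the seed is recorded in the output metadata and
a fixed seed reproduces the dataset bit for bit.

What passing tests on this generator do **not** show: anything about assay
noise (Ct values, amplification efficiency), batch effects, non-log-normal
tails, or the actual effect sizes in the original cohort. The published
fitted quantities (α = 0.71, λ = 0.01393, AUC = 0.831, the coefficient
table) came from unpublished patient data and are not reproduction targets;
the package's worked example instead verifies the one in-text computation
(e^0.21 = 1.23) and all structural properties.

## Known limitations

* **Finite-sample bias of near-unpenalized fits.** At $\lambda \to 0$ the
  fit approaches the logistic MLE, which on heavy-tailed product designs is
  biased away from zero in finite samples. In the package's recovery
  simulations (planted significant coefficients, n = 5000, λ = 10⁻⁶, 120
  replicates) the interaction estimates carry a bias of roughly +10–15% of
  their magnitude — reproduced exactly by `glm.fit` on the same designs, so
  it is a property of the estimator under these conditions, not of the
  solver. The test suite reports this honestly rather than hiding it.
* **Selection is not conservative.** See the cross-validation caveat above.
* **No assay model.** Zero-inflation, detection limits and normalization are
  out of scope; inputs are assumed to be clean relative quantities.

## Problem sizes used in the test suite

Simulation-based checks are sized to run comfortably on a single CPU: solver
oracles use 20 instances at n ≤ 50, p ≤ 4 (global optimum by sign-pattern
enumeration); recovery uses 120 replicates at n = 5000; selection behavior
uses 100 replicates each at n = 300 (planted) and n = 100 (null) on a
three-gene toy; edge classification uses 200 replicates at n = 500;
Hosmer–Lemeshow calibration uses 500 fits at n = 300. These sizes are the
package's own choices for statistical resolution.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 7)
data <- generate_dataset(cfg)

net_ht <- build_network(data, "HT")
net_lt <- build_network(data, "LT")
compare_networks(net_ht, net_lt)

tree <- hierarchical_cluster(correlation_distance(net_ht$corr))
cat(as_newick(tree))

res <- interaction_analysis(data, "LT", "HT",
                            alpha_grid = c(0.25, 0.5, 0.75, 1),
                            n_lambda = 15, lambda_min_ratio = 1e-3)
res$cv
res$fit
res$diagnostics

ratio_profile(data, "CTLA4", "CD3G")
```
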