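---
title: "Matrisome profiling of squamous lung carcinoma: models and methods"
author: "matreotypes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrisome profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matreotypes)
```

# The scientific problem

Squamous cell carcinoma (SqCC) of the lung has poor prognosis and few
actionable mutations. The extracellular matrix (ECM) of the tumor
microenvironment — the "matrisome" of collagens, proteoglycans,
glycoproteins and their regulators — is extensively remodeled during
tumorigenesis, and this remodeling carries information about both cancer
*risk* (tumor vs normal tissue, progression of pre-invasive lesions) and
*prognosis* (survival differences between ECM-defined tumor subtypes,
called matreotypes). This package implements that analysis as a tested,
reusable pipeline over bulk expression matrices with tumor/non-tumor
labels and survival annotations.

# The models

## Matrix risk score

Candidate genes are the differentially expressed core-matrisome genes
between tumor and non-tumor tissue. Genes are selected by elastic-net
penalized logistic regression (mixing parameter $\alpha = 0.5$, penalty
chosen by the one-standard-error rule on the cross-validated
misclassification error over a 100-point log-spaced $\lambda$ path from
$\lambda_{max}$ down to $10^{-4}\lambda_{max}$), and each selected gene
receives a weight from Firth-penalized logistic regression. The
per-sample score is

$$\mathrm{Risk}(s) = \sum_{i=1}^{n} z_i(s)\,\beta_i,$$

where $z_i$ is the per-gene standardized (z-scaled) log2 expression and
$\beta_i$ the log odds ratio of gene $i$. Firth's Jeffreys-prior penalty
($\ell(\beta) + \tfrac12 \log\det I(\beta)$) keeps the weights finite
under complete separation — a real concern for strongly tumor-specific
ECM genes — and reduces small-sample bias.

The weights are fitted **jointly** over the selected panel by default, so
each $\beta_i$ is adjusted for the rest of the signature; a `per_gene`
mode fits marginal single-gene models for comparison. Clinical covariates
(age, sex, stage, smoking) can be appended to the joint design; the
selection step is not re-run with covariates, only the final weight fit —
the design we judged most defensible for a covariate "correction" of a
fixed signature. Minimal signatures are found by exhaustive subset search
(when at most $10^5$ subsets) or greedy forward selection, each subset
refit with the Firth model and ranked by stratified cross-validated AUC;
ties break toward smaller subsets, then lexicographic gene order, so the
ranking is deterministic.

## Matreotype discovery

Matreotypes are discovered by Monte-Carlo reference-based consensus
clustering of the z-scaled DE core-matrisome matrix, tumors and
non-tumors together (one cluster is expected to track non-tumor tissue).
For each candidate $K$, 100 K-means runs (25 restarts each) on random 80%
sample subsets yield a consensus matrix whose ambiguity is summarized by
the PAC score — the fraction of sample pairs co-clustering with
intermediate frequency (inside $(0.1, 0.9)$). Observed PAC is compared
with `mc_iters` reference datasets drawn multivariate-normal with the
real data's gene means and gene-covariance eigenstructure, processed
identically. We report

$$\mathrm{RCSI}(K) = \ln \overline{\mathrm{PAC}}_{null}(K) -
\ln \mathrm{PAC}_{real}(K), \qquad
p(K) = \frac{1 + \#\{\mathrm{PAC}_{null} \le \mathrm{PAC}_{real}\}}
{\mathrm{mc\_iters} + 1},$$

and choose $K$ maximizing RCSI among $K$ with $p < 0.05$; with no
significant $K$ the result honestly reports "no significant structure".
Because a clean clustering attains PAC exactly 0, PAC values are floored
at $10^{-6}$ before taking logs; this log-ratio RCSI is this package's
form and is stated in the documentation rather than attributed elsewhere.
With the default 25 Monte-Carlo references the smallest attainable p is
$1/26 \approx 0.038$; fewer than 20 references can never reach
significance, which the defaults avoid.

Sample assignment uses centroids (per-matreotype mean z-scaled
expression) and minimum Euclidean distance; canonical SqCC molecular
subtypes (primitive/classical/secretory/basal) are assigned by highest
Pearson correlation with a user-supplied published centroid table, with a
low-confidence flag when even the best correlation is negative.

## Interaction and fibrosis scores

Ligand–receptor interaction strength is the product of z-scaled
expression, $R_i L_i$, for curated pairs whose ligand is a core-matrisome
gene; class- or pathway-level summaries take the **maximum** member score
per sample. Note the sign semantics: co-depletion (both z negative)
scores positive by the definition; a `truncate_negative` option
zero-truncates z first for users who want co-expression only. The
fibrosis score is the signed sum $\sum_i w_i z_i$ over a $\pm1$-weighted
gene signature of fibrotic lung. Both are linear in z and exactly
reproducible by hand on toy inputs, which the test suite exploits.

## Survival and association statistics

Kaplan–Meier estimates with the k-group log-rank test (asymptotic
$\chi^2$; degrees of freedom reduced when a group has no events), Cox
proportional hazards with Efron tie handling and Wald 95% intervals
(reference level = first sorted label, e.g. ECM-Low), Fisher's exact test
in the two-sided sum-of-small-probabilities convention, and Mann-Whitney
tests (exact for groups of up to 8 without ties, tie-corrected normal
approximation otherwise) with Benjamini-Hochberg correction applied
within each analysis family.

# The synthetic cohort generator

Because the original cohorts are controlled-access or large external
downloads, validation runs on synthetic cohorts whose generative truth is
recorded. The generator emulates exactly the structures the analysis
relies on:

- a latent per-gene log2 layer: baselines uniform on $[3, 8]$, unit
  latent SD, equicorrelated gene blocks (a draw
  $\sqrt{\rho}\,u_s + \sqrt{1-\rho}\,\varepsilon_{gs}$ gives exact
  compound symmetry for $\rho \in [0,1)$, mirroring correlated
  core-matrisome programs);
- planted signature genes shifted by `effect_size_sd_units` (default 1
  log2-SD) in tumors, half up and half down;
- an ECM-program block additionally shifted in ECM-High tumors, so the
  two matreotypes differ in a coherent program rather than scattered
  genes — this block genuinely separates tumor from normal as well, as a
  real ECM program would;
- negative-binomial counts around $2^{\mathrm{latent}}$ with variance
  $\mu + \phi\mu^2$ ($\phi = 0.2$, a typical bulk biological
  overdispersion) and per-sample library factors uniform on
  $[0.7, 1.3]$;
- exponential survival in months (baseline hazard 0.02/month, a median
  of about 35 months, in the range of SqCC cohorts) multiplied by
  $e^{\log HR}$ for ECM-High; censoring combines an exponential component
  calibrated so the expected censored fraction matches `censor_rate`
  with an administrative horizon (240 months default);
- premalignant lesions drawn from the non-tumor profile with the risk
  genes moved toward the tumor profile by a configurable fraction of the
  planted effect.

One root seed spawns six fixed substreams (gene template, expression,
survival, censoring, library sizes, premalignant cohort), so adding a
stage never perturbs earlier draws and identical config + seed is
byte-identical.

What the generator does **not** emulate: batch effects, gene-length or
GC biases, non-exponential hazards, dependence between censoring and
covariates, and single-cell dropout. Passing tests therefore demonstrate
that the pipeline recovers the structures it models under realistic
noise, not that it is robust to every artifact of real cohorts.

# Numerical choices

- Count filter: `min_count = 10` in at least `min_prop = 0.2` of samples
  (common practice for the normalization tool used); TMM trims 30% of
  M-values and 5% of A-values with precision weights; log2(CPM + 0.5)
  avoids $-\infty$ on zero counts.
- External cohorts are re-z-scaled within their own cohort by default; a
  stored reference model (`writeZScaleModel`/`readZScaleModel`) projects
  instead when cross-cohort score comparability matters. The source
  analyses are ambiguous on this point; per-cohort scaling is the safer
  default because it removes platform-scale differences.
- Differential expression is an unpaired two-group moderated test; the
  matched-pair structure of some source cohorts is not modeled.
- `prior_df = 0` in `differentialExpression` disables moderation and
  reproduces the ordinary pooled t-test exactly — used as an internal
  oracle in the tests.
- The Firth Newton solver targets a score norm below $10^{-8}$ with
  step-halving, accepts a stationary step at float resolution
  ($|\Delta\beta| < 10^{-10}$), and errors only when the residual
  gradient exceeds $10^{-4}$.
- Centroid-assignment distance ties and refinement-AUC ties break
  deterministically (first sorted label; smaller subset, then
  lexicographic order).
- Spearman correlation p-values use the asymptotic t approximation;
  significance is BH-adjusted over the upper triangle.
- The per-sample rank-enrichment score uses the weighted KS running sum
  with exponent 0.25 on rank weights, normalized by each set's score
  range over samples; it is a rank-based single-sample enrichment
  statistic labelled by its method tag, chosen for determinism and
  transform-invariance rather than bit-level agreement with any
  kernel-density variant.

# Validation problem sizes

The packaged tests and `scripts/acceptance.R` validate, per run: signature
recovery on ten synthetic cohorts of 2000 genes and 280 samples (20
planted genes at 1 SD), matreotype recovery on five 60-sample cohorts of
three 6-SD-separated clusters plus five pure-noise cohorts, hazard-ratio
recovery on ten cohorts of 300 tumors per arm at log HR = ln 2 with 20%
censoring, and type-I calibration of the moderated tests on fully null
generator configurations. These sizes were chosen so every planted
quantity is estimable with comfortable margins while each stage remains a
routine desktop computation.

# Known limitations

- The published 28-gene signature and the exact TCGA matreotype labels
  require the original cohorts; the package validates the *procedure* on
  synthetic truth, reproducing published values only where the paper
  prints its inputs (the subtype contingency table and gene counts).
- Consensus clustering cost grows as `|k_range| * (mc_iters + 1) *
  resamples` K-means runs; for cohorts of thousands of samples reduce
  `nstart` or `resamples` before widening `k_range`.
- The ligand-receptor module scores transcriptional co-occurrence in
  bulk tissue; it cannot attribute signaling to cell types and treats
  co-depletion as positive interaction strength unless truncated.
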