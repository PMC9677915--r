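# matreotypes

ECM (matrisome) expression profiling for squamous cell lung carcinoma:
matrix risk signatures, prognostic ECM tumor subtypes ("matreotypes"),
and the surrounding statistics, as a tested R package.

## The problem

Squamous cell carcinoma (SqCC) of the lung lacks actionable mutations,
and its prognosis is poor even for resected early-stage disease. The
extracellular matrix of the tumor microenvironment is heavily remodeled
during tumorigenesis, and that remodeling is informative twice over:
matrisome genes separate tumor from normal lung (and progressive from
regressive pre-invasive lesions), and ECM-defined tumor subtypes differ
in survival. This package implements the full analysis path for bulk
RNA-seq cohorts with tumor/non-tumor labels and survival annotations. It
is aimed at computational biologists who want to derive or apply
ECM-based risk and prognosis models on their own cohorts, with every
stage unit-tested against independent oracles and validated end-to-end
on synthetic cohorts with known truth.

## The models

**Matrix risk score.** Differentially expressed core-matrisome genes
(moderated two-group test, BH < 0.05) are pruned by elastic-net
penalized logistic regression (α = 0.5, λ by the one-standard-error rule
on cross-validated prediction error), and each selected gene *i* gets a
weight β<sub>i</sub> = log(odds ratio) from Firth-penalized logistic
regression (finite even under complete separation). The per-sample score
is

> Risk(s) = Σ<sub>i</sub> z<sub>i</sub>(s) · β<sub>i</sub>

on per-gene standardized (z-scaled) log2 expression, validated by ROC
analysis on a held-out stratified partition.

**Matreotypes.** Monte-Carlo reference-based consensus clustering
(repeated subsampled K-means; PAC ambiguity score; RCSI and Monte-Carlo
p-values against covariance-preserving Gaussian reference data) selects
the number of ECM subtypes; samples are assigned by minimum Euclidean
distance to per-subtype centroids, and survival differences are tested
with Kaplan–Meier/log-rank and Cox proportional-hazards models (Efron
ties, age/stage adjustment). Canonical SqCC subtypes
(primitive/classical/secretory/basal) are assigned by highest Pearson
correlation with published centroids, with matreotype association tested
by Fisher's exact test.

**Ligand–receptor and set scores.** Interaction strength R<sub>i</sub> ·
L<sub>i</sub> on z-scaled expression for curated core-matrisome
ligand–receptor pairs, aggregated to receptor classes or pathways by the
member maximum and contrasted between matreotypes with the same
moderated-test machinery; single-sample rank-enrichment scores, a
±1-weighted fibrosis score Σ w<sub>i</sub> z<sub>i</sub>, and per-cell
module scores with expression-matched control genes.

A seeded synthetic-cohort generator (negative-binomial counts over a
block-correlated log2 latent layer, planted signature genes, planted
matreotypes with a survival hazard ratio, premalignant lesions) makes
the whole pipeline testable without controlled-access data.

## Worked example

```r
library(matreotypes)

cfg <- syntheticConfig(n_tumor = 120L, n_non_tumor = 30L,
                       n_genes_total = 1000L, n_matrisome = 300L,
                       n_signature = 20L, planted_log_hr = log(2),
                       seed = 42L)
sim    <- simulateBulkCohort(cfg)
log2se <- tmmNormalizeLog2(sim$se)
cls    <- sim$metadata$tissue_class

core <- sim$truth_genes$gene[!is.na(sim$truth_genes$division) &
                             sim$truth_genes$division == "core_matrisome"]
de <- differentialExpression(log2se[intersect(core, rownames(log2se)), ], cls)
z  <- zscaleGenes(log2se)

part <- partitionCohort(setNames(cls, sim$metadata$sample_id), 0.8, seed = 42)
ctr  <- cls[match(part$train, sim$metadata$sample_id)]
sel  <- elasticNetSelect(zValues(z)[de$gene[de$significant], part$train],
                         ctr, seed = 42)
sig  <- firthLogOdds(zValues(z)[, part$train], ctr, genes = sel$genes,
                     positive = "tumor")
scores <- matrixRiskScore(zValues(z)[, part$test], sig)
cte    <- cls[match(part$test, sim$metadata$sample_id)]
rocAuc(scores, cte, positive = "tumor")$auc

truthTypes <- setNames(sim$truth_samples$matreotype, sim$truth_samples$sample)
model    <- buildCentroids(zValues(z), truthTypes[colnames(sim$se)])
assigned <- centroidAssign(zValues(z), model)
coxPH(sim$survival, assigned[rownames(sim$survival)],
      covariates = c("age_years", "stage"), reference = "ECM_Low")
```

This prints (seed 42):

```
DE core-matrisome genes: 32 of 150
elastic net selected 24 genes at lambda_1se = 0.0204
held-out AUC (tumor vs non-tumor): 0.993
           truth
assigned    ECM_High ECM_Low Non_Tumor
  ECM_High        55       6         1
  ECM_Low          4      54         0
  Non_Tumor        1       0        29
       term    HR ci_lo ci_hi       p
1  ECM_High 1.783 1.172  2.71 0.00688
2 Non_Tumor 3.766 0.507 27.97 0.19492
3 age_years 0.996 0.970  1.02 0.76457
4     stage 1.154 0.946  1.41 0.15737
```

Reading it: 32 of 150 core-matrisome genes separate tumor from
non-tumor; the elastic net keeps 24 of them; the Firth-weighted risk
score separates held-out tumor from non-tumor tissue with AUC 0.993
(the cohort plants a 1-SD effect on 20 signature genes). Centroid
assignment recovers the planted matreotypes almost perfectly, and the
ECM-High matreotype carries a hazard ratio of 1.78 (95% CI 1.17–2.71)
relative to ECM-Low, adjusted for age and stage, against a planted
hazard ratio of 2. For matreotype *discovery* (unknown labels), use
`consensusCluster()` on the z-scaled DE core-matrisome matrix; it
selects the cluster number by PAC/RCSI with a Monte-Carlo significance
gate and returns labels only when the structure beats the null.

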