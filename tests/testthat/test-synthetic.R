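test_that("generation is deterministic in config+seed and varies across seeds", {
  a <- small_cohort(seed = 11)
  b <- small_cohort(seed = 11)
  expect_identical(exprValues(a$se), exprValues(b$se))
  expect_identical(a$metadata, b$metadata)
  c <- small_cohort(seed = 12)
  expect_false(identical(exprValues(a$se), exprValues(c$se)))
  # truth structure (gene roles, layout) is seed-invariant
  expect_identical(a$truth_genes$role, c$truth_genes$role)
})

test_that("counts are non-negative integers with library factors in range", {
  sim <- small_cohort(seed = 3)
  m <- exprValues(sim$se)
  expect_true(all(m >= 0))
  expect_true(all(m == floor(m)))
  rng <- sim$config$library_size_range
  expect_true(all(sim$truth_samples$size_factor >= rng[1] &
                    sim$truth_samples$size_factor <= rng[2]))
})

test_that("planted tumor effect is recovered at the configured magnitude", {
  cfg <- syntheticConfig(n_tumor = 200L, n_non_tumor = 60L,
                         n_genes_total = 500L, n_matrisome = 300L,
                         n_signature = 20L, effect_size_sd_units = 1,
                         seed = 5)
  sim <- simulateBulkCohort(cfg)
  lg <- exprValues(tmmNormalizeLog2(sim$se))
  tum <- sim$metadata$tissue_class == "tumor"
  truth <- sim$truth_genes
  planted <- truth[truth$role %in% c("sig_up", "sig_dn"), ]
  diffs <- rowMeans(lg[planted$gene, tum]) - rowMeans(lg[planted$gene, !tum])
  # signed mean difference should sit at the planted 1.0 log2-SD shift
  expect_lt(abs(mean(diffs * sign(planted$tumor_shift_sd)) - 1), 0.15)
})

test_that("latent block correlations match the configured rho", {
  cfg <- syntheticConfig(n_tumor = 200L, n_non_tumor = 40L,
                         n_genes_total = 300L, n_matrisome = 200L,
                         block_spec = list(c(20, 0.8), c(15, 0.4)),
                         n_signature = 10L, seed = 2)
  template <- matreotypes:::.geneTemplate(cfg)
  set.seed(99)
  z <- matreotypes:::.latentNoise(template, 240L)
  for (b in 1:2) {
    idx <- which(template$block == b)
    rho <- cfg$block_spec[[b]][2]
    cors <- cor(t(z[idx, ]))
    emp <- mean(cors[upper.tri(cors)])
    expect_lt(abs(emp - rho), 0.1)
  }
  # off-block genes uncorrelated
  off <- cor(t(z[template$block == 0, ][1:20, ]))
  expect_lt(max(abs(off[upper.tri(off)])), 0.35)
})

test_that("censoring fraction tracks censor_rate", {
  for (cr in c(0.2, 0.5)) {
    cfg <- syntheticConfig(n_tumor = 400L, n_non_tumor = 40L,
                           n_genes_total = 60L, n_matrisome = 50L,
                           n_signature = 4L, block_spec = list(c(10, 0.5)),
                           censor_rate = cr, seed = 7)
    sim <- simulateBulkCohort(cfg)
    cens <- 1 - mean(sim$survival$event)
    expect_lt(abs(cens - cr), 0.1)
  }
})

test_that("a null configuration carries no survival or expression signal", {
  cfg <- syntheticConfig(n_tumor = 100L, n_non_tumor = 60L,
                         n_genes_total = 400L, n_matrisome = 200L,
                         n_signature = 10L, effect_size_sd_units = 0,
                         planted_log_hr = 0, seed = 21)
  sim <- simulateBulkCohort(cfg)
  de <- differentialExpression(tmmNormalizeLog2(sim$se),
                               sim$metadata$tissue_class)
  expect_lt(mean(de$p_value < 0.05), 0.10)
  expect_gt(mean(de$p_value < 0.05), 0.015)
  labels <- sim$truth_samples$matreotype[sim$truth_samples$tissue_class == "tumor"]
  cx <- coxPH(sim$survival, labels)
  expect_lt(abs(cx$coef[1]), 0.45)
})

test_that("degenerate configurations are rejected", {
  expect_error(syntheticConfig(block_spec = list(c(10, 1.0))), "\\[0, 1\\)")
  expect_error(syntheticConfig(matreotype_fraction = 1), "matreotype_fraction")
  expect_error(syntheticConfig(n_signature = 0), "positive")
  expect_error(syntheticConfig(n_matrisome = 5000), "exceeds|fit inside")
})

test_that("premalignant cohorts respond to the shift fraction", {
  cfg <- syntheticConfig(n_tumor = 60L, n_non_tumor = 20L,
                         n_genes_total = 300L, n_matrisome = 200L,
                         n_signature = 10L,
                         block_spec = list(c(20, 0.7), c(15, 0.5)),
                         seed = 31)
  sim <- simulateBulkCohort(cfg)
  riskGenes <- sim$truth_genes$gene[sim$truth_genes$role %in%
                                      c("sig_up", "sig_dn")]
  expect_error(simulatePremalignantCohort(cfg, character(0)), "non-empty")
  expect_error(simulatePremalignantCohort(cfg, "NOT_A_GENE"), "universe")

  # train a signature on the bulk cohort, score the lesions
  z <- zscaleGenes(tmmNormalizeLog2(sim$se))
  sig <- firthLogOdds(z, sim$metadata$tissue_class, genes = riskGenes,
                      positive = "tumor")
  scoreAuc <- function(shift) {
    pm <- simulatePremalignantCohort(cfg, riskGenes, shift_fraction = shift,
                                     n_per_group = 30L)
    zpm <- zscaleGenes(tmmNormalizeLog2(pm$se, min_count = 1, min_prop = 0.1))
    sc <- matrixRiskScore(zpm, sig)
    rocAuc(sc, pm$labels, positive = "progressive")$auc
  }
  expect_gte(scoreAuc(1), 0.95)
  expect_lt(abs(scoreAuc(0) - 0.5), 0.2)
})
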