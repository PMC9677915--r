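surv_df <- function(time, event, ...) {
  data.frame(sample_id = sprintf("s%03d", seq_along(time)),
             time_months = time, event = event, ...)
}

test_that("log-rank matches a hand-enumerated O-E/V computation", {
  # group A: events at 1, 2; group B: events at 3, 4
  surv <- surv_df(c(1, 2, 3, 4), c(1, 1, 1, 1))
  groups <- c("A", "A", "B", "B")
  # hand enumeration over the 4 event-time tables (O - E and V for group A):
  # t=1: at risk 4 (2 A), O=1, E=2/4,   V=(2*2*1*3)/(16*3)=0.25
  # t=2: at risk 3 (1 A), O=1, E=1/3,   V=(1*2*1*2)/(9*2)=2/9
  # t=3: at risk 2 (0 A), O=0, E=0,     V=0
  # t=4: at risk 1 (0 A), O=0, E=0,     V=0
  OmE <- (1 - 2 / 4) + (1 - 1 / 3)
  V <- 0.25 + 2 / 9
  chisqHand <- OmE^2 / V
  res <- kmLogrank(surv, groups)
  expect_equal(res$chisq, chisqHand, tolerance = 1e-9)
  expect_equal(res$p, pchisq(chisqHand, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("log-rank on duplicated groups is exactly null and KM is an ECDF", {
  base <- surv_df(c(2, 5, 7, 11, 3, 8), c(1, 1, 0, 1, 1, 1))
  surv <- rbind(base, base)
  groups <- rep(c("A", "B"), each = 6)
  res <- kmLogrank(surv, groups)
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)

  # with no censoring, KM equals the empirical survival function
  s2 <- surv_df(c(1, 2, 3, 4, 5), rep(1, 5))
  res2 <- kmLogrank(rbind(s2, s2), rep(c("A", "B"), each = 5))
  kmA <- res2$km[res2$km$group == "A", ]
  expect_equal(kmA$survival, 1 - seq_len(5) / 5, tolerance = 1e-12)
  expect_true(all(diff(kmA$survival) <= 1e-12))

  # zero-event group triggers the df warning
  s3 <- surv_df(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_warning(kmLogrank(s3, c("A", "A", "B", "B")), "zero events")
})

test_that("Cox estimates respect label symmetry and tie-handling equivalence", {
  set.seed(70)
  n <- 400
  g <- rep(c("lo", "hi"), each = n / 2)
  t0 <- rexp(n, 0.02 * ifelse(g == "hi", 2, 1))
  cens <- rexp(n, 0.005)
  surv <- surv_df(pmin(t0, cens) + 1e-9, as.numeric(t0 <= cens))
  fit <- coxPH(surv, g, reference = "lo")
  fitSwap <- coxPH(surv, g, reference = "hi")
  expect_equal(fit$coef, -fitSwap$coef, tolerance = 1e-8)
  expect_true(fit$HR > 0)
  expect_true(fit$ci_lo <= fit$HR && fit$HR <= fit$ci_hi)

  # continuous times: Efron and Breslow agree when there are no ties
  fitE <- coxPH(surv, g, reference = "lo", ties = "efron")
  fitB <- coxPH(surv, g, reference = "lo", ties = "breslow")
  expect_equal(fitE$coef, fitB$coef, tolerance = 1e-8)

  # two identical arms: coefficient pinned near zero
  survDup <- rbind(surv, surv)
  gDup <- rep(c("A", "B"), each = n)
  fit0 <- coxPH(survDup, gDup)
  expect_lt(abs(fit0$coef[1]), 0.1)
})

test_that("Cox recovers a planted hazard ratio with covariate adjustment", {
  cfg <- syntheticConfig(n_tumor = 300L, n_non_tumor = 20L,
                         n_genes_total = 60L, n_matrisome = 50L,
                         n_signature = 4L, block_spec = list(c(10, 0.5)),
                         planted_log_hr = log(2), censor_rate = 0.2,
                         seed = 41)
  sim <- simulateBulkCohort(cfg)
  labels <- sim$truth_samples$matreotype[
    sim$truth_samples$tissue_class == "tumor"]
  fit <- coxPH(sim$survival, labels, covariates = c("age_years", "stage"),
               reference = "ECM_Low")
  row <- fit[fit$term == "ECM_High", ]
  expect_gt(row$coef, 0.4)
  expect_lt(row$coef, 1.0)
  expect_true(all(c("age_years", "stage") %in% fit$term))
})

test_that("Fisher enrichment matches full hypergeometric enumeration", {
  # [[3,1],[1,3]] -> two-sided p = 34/70
  a <- rep(c("x", "y"), c(4, 4))
  b <- c(rep("cat", 3), "other", "cat", rep("other", 3))
  res <- fisherEnrichment(a, b)
  row <- res[res$category == "cat", ]
  expect_equal(row$p_value, 34 / 70, tolerance = 1e-12)

  # random tables with N <= 40 against the enumeration oracle
  set.seed(71)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    a <- sample(c("u", "v"), n, replace = TRUE, prob = c(0.4, 0.6))
    b <- sample(c("p", "q"), n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    res <- fisherEnrichment(a, b)
    tab <- rbind(table(factor(a, c("u", "v"))[b == "p"]),
                 table(factor(a, c("u", "v"))[b != "p"]))
    expect_equal(res$p_value[res$category == "p"], fisher2x2_oracle(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisherEnrichment(rep("x", 4), c("p", "q", "p", "q")),
               "2 levels")
})

test_that("rank-sum comparisons are exact for small groups and flag constants", {
  vals <- rbind(V1 = c(1, 2, 3, 4, 5, 6),
                V2 = c(7, 7, 7, 7, 7, 7),
                V3 = c(2, 4, 9, 1, 8, 3))
  colnames(vals) <- sprintf("s%d", 1:6)
  groups <- rep(c("a", "b"), each = 3)
  res <- groupCompareBH(vals, groups)
  # (1,2,3) vs (4,5,6): U = 0, exact two-sided p = 0.1
  expect_equal(res$U[res$variable == "V1"], 0)
  expect_equal(res$p_value[res$variable == "V1"], 0.1, tolerance = 1e-12)
  expect_true(res$constant[res$variable == "V2"])
  expect_equal(res$p_value[res$variable == "V2"], 1)
  expect_true(all(res$adj_p_value >= res$p_value - 1e-12))
  expect_true(all(res$adj_p_value <= 1))
})
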