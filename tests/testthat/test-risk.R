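test_that("cohort partitioning is stratified, deterministic and exhaustive", {
  classes <- setNames(rep(c("tumor", "non_tumor"), c(100, 20)),
                      sprintf("s%03d", 1:120))
  p <- partitionCohort(classes, 0.8, seed = 1)
  expect_length(p$train, 96L)
  expect_equal(sum(classes[p$train] == "tumor"), 80L)
  expect_equal(sum(classes[p$train] == "non_tumor"), 16L)
  expect_length(intersect(p$train, p$test), 0L)
  expect_setequal(c(p$train, p$test), names(classes))
  expect_identical(partitionCohort(classes, 0.8, seed = 1), p)

  # proportions exact for every seed
  for (s in seq_len(1000)) {
    ps <- partitionCohort(classes, 0.8, seed = s)
    expect_equal(sum(classes[ps$train] == "tumor"), 80L)
  }
  expect_error(partitionCohort(classes, 1.2), "\\(0, 1\\)")
})

test_that("elastic net zeroes out at lambda_max and finds a separating gene", {
  set.seed(30)
  n <- 60
  classes <- rep(c("non_tumor", "tumor"), each = n / 2)
  m <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(sprintf("G%02d", 1:40), sprintf("s%02d", 1:n)))
  m["G07", ] <- ifelse(classes == "tumor", 2, -2) + rnorm(n, sd = 0.1)
  sel <- elasticNetSelect(m, classes, folds = 5, seed = 1)
  expect_true("G07" %in% sel$genes)
  # by definition of lambda_max, the largest path lambda selects nothing
  expect_equal(unname(sel$fit$nzero[1]), 0L)
  idx <- c(1:6, 31:36)  # 6 per class, fewer than 10 folds
  expect_error(elasticNetSelect(m[, idx], classes[idx], folds = 10),
               "folds")
})

test_that("Firth fits match a brute-force penalized-likelihood oracle under separation", {
  # complete separation: ML diverges, Firth stays finite
  x <- c(-1, -1, 1, 1)
  y <- c(0, 0, 1, 1)
  fit <- matreotypes:::.firthFit(cbind(x), y)
  expect_true(is.finite(fit$beta))

  pen <- function(b) {
    eta <- x * b
    sum(y * eta - log1p(exp(eta))) +
      0.5 * log(sum(plogis(eta) * (1 - plogis(eta)) * x^2))
  }
  grid <- seq(-5, 5, by = 1e-4)
  bOracle <- grid[which.max(vapply(grid, pen, numeric(1)))]
  expect_equal(unname(fit$beta), bOracle, tolerance = 1e-4)
})

test_that("Firth estimates are near-null for null genes and consistent for real effects", {
  set.seed(31)
  n <- 2000
  xNull <- rnorm(n)
  xTrue <- rnorm(n)
  yTrue <- rbinom(n, 1, plogis(xTrue * 1.0))
  m <- rbind(NULLGENE = xNull, TRUEGENE = xTrue)
  colnames(m) <- sprintf("s%04d", 1:n)
  sig <- firthLogOdds(m, ifelse(yTrue == 1, "tumor", "non_tumor"),
                      mode = "per_gene", positive = "tumor")
  expect_lt(abs(signatureWeights(sig)["NULLGENE"]), 0.05)
  expect_gt(signatureWeights(sig)["TRUEGENE"], 0.8)
  expect_lt(signatureWeights(sig)["TRUEGENE"], 1.2)
})

test_that("Firth stays finite on separable panels where ML diverges", {
  set.seed(32)
  classes <- rep(c("non_tumor", "tumor"), each = 10)
  m <- matrix(rnorm(3 * 20), 3, 20,
              dimnames = list(c("A", "B", "C"), sprintf("s%02d", 1:20)))
  m["A", ] <- ifelse(classes == "tumor", 1, -1)  # perfect separator
  sig <- firthLogOdds(m, classes, positive = "tumor")
  expect_true(all(is.finite(signatureWeights(sig))))
})

test_that("the matrix risk score is the exact weighted sum and is linear", {
  z <- matrix(c(1, -1, 2), 3, 1,
              dimnames = list(c("A", "B", "C"), "s1"))
  sig <- new("RiskSignature", genes = c("A", "B", "C"),
             beta = c(A = 0.5, B = -0.25, C = 1.0), provenance = list())
  expect_equal(unname(matrixRiskScore(z, sig)), 2.75, tolerance = 1e-12)

  z0 <- matrix(0, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(unname(matrixRiskScore(z0, sig)), c(0, 0))

  one <- matrix(1, 1, 1, dimnames = list("A", "s1"))
  sigLn2 <- new("RiskSignature", genes = "A", beta = c(A = log(2)),
                provenance = list())
  expect_equal(unname(matrixRiskScore(one, sigLn2)), 0.6931, tolerance = 1e-4)

  # linearity: scaling the weights scales the score
  sig3 <- new("RiskSignature", genes = sig@genes, beta = 3 * sig@beta,
              provenance = list())
  expect_equal(matrixRiskScore(z, sig3), 3 * matrixRiskScore(z, sig),
               tolerance = 1e-12)
  expect_error(matrixRiskScore(z[1:2, , drop = FALSE], sig), "missing")
})

test_that("AUC matches brute-force pair counting and its invariances", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  classes <- c("neg", "neg", "pos", "pos")
  expect_equal(rocAuc(scores, classes, positive = "pos")$auc, 0.75)
  expect_equal(rocAuc(scores, classes, positive = "pos")$auc,
               auc_oracle(scores, classes == "pos"))

  expect_equal(rocAuc(c(1, 2, 3, 10, 11), rep(c("neg", "pos"), c(3, 2)),
                      positive = "pos")$auc, 1)
  expect_equal(rocAuc(rep(2, 6), rep(c("neg", "pos"), 3),
                      positive = "pos")$auc, 0.5)

  set.seed(33)
  s <- rnorm(40)
  cl <- sample(c("neg", "pos"), 40, replace = TRUE)
  expect_equal(rocAuc(s, cl, positive = "pos")$auc,
               auc_oracle(s, cl == "pos"), tolerance = 1e-12)
  # invariant under strictly increasing transforms
  expect_equal(rocAuc(exp(s), cl, positive = "pos")$auc,
               rocAuc(s, cl, positive = "pos")$auc, tolerance = 1e-12)
  # curve is monotone and AUC matches its trapezoidal integral
  rc <- rocAuc(s, cl, positive = "pos")
  expect_true(all(diff(rc$curve$tpr) >= -1e-12))
  expect_true(all(diff(rc$curve$fpr) >= -1e-12))
  trap <- sum(diff(rc$curve$fpr) *
                (head(rc$curve$tpr, -1) + tail(rc$curve$tpr, -1)) / 2)
  expect_equal(trap, rc$auc, tolerance = 1e-9)
})

test_that("minimal-signature refinement finds the informative genes", {
  set.seed(34)
  n <- 80
  classes <- rep(c("non_tumor", "tumor"), each = n / 2)
  tum <- classes == "tumor"
  m <- matrix(rnorm(5 * n, sd = 1), 5, n,
              dimnames = list(c("INF1", "INF2", "N1", "N2", "N3"),
                              sprintf("s%02d", 1:n)))
  m["INF1", tum] <- m["INF1", tum] + 2
  m["INF2", tum] <- m["INF2", tum] - 2
  sig <- firthLogOdds(m, classes, positive = "tumor")
  ref <- refineMinimalSignature(m, sig, classes, max_size = 2, seed = 1)
  expect_identical(ref$subset[1], "INF1,INF2")
  ref1 <- refineMinimalSignature(m, sig, classes, max_size = 1, seed = 1)
  expect_true(ref1$subset[1] %in% c("INF1", "INF2"))
  expect_true(all(diff(ref$cv_auc) <= 1e-12))
  expect_error(refineMinimalSignature(m, sig, classes, max_size = 0),
               "max_size")
})
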