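# Independent enumeration of the weighted KS running-sum statistic
ks_oracle <- function(expr_col, set_genes, tau = 0.25) {
  ranks <- rank(expr_col, ties.method = "average")
  ord <- names(sort(ranks, decreasing = TRUE))
  inSet <- ord %in% set_genes
  w <- ranks[ord]^tau
  pin <- cumsum(ifelse(inSet, w, 0)) / sum(w[inSet])
  pout <- cumsum(!inSet) / sum(!inSet)
  sum(pin - pout)
}

test_that("rank enrichment equals the hand-enumerated running sum", {
  set.seed(80)
  m <- matrix(rnorm(10 * 4, 6), 10, 4,
              dimnames = list(sprintf("G%02d", 1:10), paste0("s", 1:4)))
  set <- c("G02", "G05", "G09")
  # compute un-normalized statistics per sample via the oracle
  es <- vapply(colnames(m), function(s) ks_oracle(m[, s], set), numeric(1))
  suppressWarnings(
    sc <- geneSetScore(ExpressionMatrix(m, unit = "log2"),
                       list(myset = c(set, "G01", "G03"))))
  # scores are the oracle statistics for the 5-gene set, range-normalized
  es5 <- vapply(colnames(m), function(s)
    ks_oracle(m[, s], c(set, "G01", "G03")), numeric(1))
  expect_equal(unname(sc["myset", ]), unname(es5 / diff(range(es5))),
               tolerance = 1e-9)
})

test_that("extreme and interleaved rankings behave as expected", {
  g <- sprintf("G%02d", 1:20)
  top <- c(20:16, sample(15:1))          # set genes occupy the top ranks
  uniform <- seq(20, 1, by = -1)
  m <- cbind(extreme = top, other1 = sample(20), other2 = sample(20))
  rownames(m) <- g
  set <- g[1:5]
  sc <- geneSetScore(ExpressionMatrix(m, unit = "log2"), list(s = set))
  expect_equal(colnames(sc)[which.max(sc["s", ])], "extreme")
})

test_that("gene-set scoring is rank-based, so monotone transforms change nothing", {
  set.seed(81)
  m <- matrix(rexp(30 * 6) + 1, 30, 6,
              dimnames = list(sprintf("G%02d", 1:30), paste0("s", 1:6)))
  sets <- list(a = sprintf("G%02d", c(1, 4, 7, 10, 13)),
               b = sprintf("G%02d", c(2, 8, 14, 20, 26)))
  s1 <- geneSetScore(ExpressionMatrix(m, unit = "log2"), sets)
  s2 <- geneSetScore(ExpressionMatrix(log2(m), unit = "log2"), sets)
  expect_equal(s1, s2, tolerance = 1e-12)
  # small sets skipped with a warning; empty collection errors
  expect_warning(
    geneSetScore(ExpressionMatrix(m, unit = "log2"),
                 list(a = sets$a, tiny = c("G01", "G02"))), "skipping")
  expect_error(geneSetScore(ExpressionMatrix(m, unit = "log2"), list()),
               "empty")
})

test_that("fibrosis score is the exact signed sum and is linear", {
  z <- matrix(c(1, 2, 1), 3, 1, dimnames = list(c("UP1", "UP2", "DN1"), "s1"))
  sig <- data.frame(gene = c("UP1", "UP2", "DN1"), weight = c(1, 1, -1))
  expect_equal(unname(fibrosisScore(z, sig)), 2, tolerance = 1e-12,
               ignore_attr = TRUE)

  z0 <- matrix(0, 3, 2,
               dimnames = list(c("UP1", "UP2", "DN1"), c("s1", "s2")))
  expect_equal(unname(fibrosisScore(z0, sig)), c(0, 0), ignore_attr = TRUE)

  sigNeg <- transform(sig, weight = -weight)
  expect_equal(fibrosisScore(z, sigNeg), -fibrosisScore(z, sig),
               tolerance = 1e-12, ignore_attr = TRUE)

  # missing genes counted; zero overlap errors
  sig2 <- rbind(sig, data.frame(gene = "ABSENT", weight = 1))
  expect_equal(attr(fibrosisScore(z, sig2), "n_missing"), 1L)
  expect_error(fibrosisScore(z, data.frame(gene = "X", weight = 1)),
               "no fibrosis")

  # gene-order invariance
  expect_equal(fibrosisScore(z[c(3, 1, 2), , drop = FALSE], sig),
               fibrosisScore(z, sig), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("module scores are seeded, centered for random sets, and track shifts", {
  set.seed(82)
  nGenes <- 600; nCells <- 50
  base <- rnorm(nGenes, 5, 2)
  m <- matrix(rnorm(nGenes * nCells, base), nGenes, nCells,
              dimnames = list(sprintf("G%03d", 1:nGenes),
                              sprintf("c%02d", 1:nCells)))
  randomSet <- sample(rownames(m), 20)
  s1 <- moduleScore(m, randomSet, seed = 9)
  expect_identical(s1, moduleScore(m, randomSet, seed = 9))
  expect_lt(abs(mean(s1)), 0.3)

  # +1 shift of the set genes in a subset of cells: those cells score
  # about one unit above the rest (global averages, hence the control
  # matching, stay nearly unchanged)
  m2 <- m
  shifted <- 1:5
  m2[randomSet, shifted] <- m2[randomSet, shifted] + 1
  s2 <- moduleScore(m2, randomSet, seed = 9)
  expect_lt(abs(mean(s2[shifted]) - mean(s2[-shifted]) - 1), 0.3)
  expect_error(moduleScore(m, rownames(m)), "control")
})

test_that("all scoring methods rank a planted subgroup higher", {
  set.seed(83)
  nGenes <- 200
  m <- matrix(rnorm(nGenes * 40, 6), nGenes, 40,
              dimnames = list(sprintf("G%03d", 1:nGenes),
                              sprintf("s%02d", 1:40)))
  set <- sprintf("G%03d", 1:15)
  shifted <- 1:20
  m[set, shifted] <- m[set, shifted] + 1.5
  se <- ExpressionMatrix(m, unit = "log2")
  for (method in c("rank_enrichment", "weighted_z", "module_score")) {
    sc <- geneSetScore(se, list(s = set), method = method, seed = 4)
    expect_gt(mean(sc["s", shifted]), mean(sc["s", -shifted]))
    expect_identical(attr(sc, "method"), method)
  }
})
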