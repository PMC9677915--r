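# Shared fixtures and small independent oracles used across the suite.

# adjusted Rand index between two labelings (independent of any package)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  scl <- sum(choose(colSums(tab), 2))
  ex <- sr * scl / choose(n, 2)
  (sc - ex) / ((sr + scl) / 2 - ex)
}

# three well-separated spherical Gaussian blobs, genes x samples
make_blobs <- function(seed, sep = 6, n_per = 20L, n_genes = 30L) {
  set.seed(seed + 1000)
  n <- 3L * n_per
  labels <- rep(1:3, each = n_per)
  m <- matrix(rnorm(n_genes * n), n_genes, n)
  m[1:5, labels == 2] <- m[1:5, labels == 2] + sep
  m[6:10, labels == 3] <- m[6:10, labels == 3] + sep
  dimnames(m) <- list(sprintf("G%02d", seq_len(n_genes)),
                      sprintf("S%02d", seq_len(n)))
  list(m = m, labels = labels)
}

# a small expression TSV on disk; returns the path
write_expr_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# brute-force two-sided Fisher p for a 2x2 table: sum of hypergeometric
# probabilities of all tables (with the observed margins) whose probability
# does not exceed the observed one
fisher2x2_oracle <- function(tab) {
  m <- sum(tab[, 1])
  n <- sum(tab[, 2])
  k <- sum(tab[1, ])
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# brute-force AUC by concordant-pair counting with half-credit for ties
auc_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small tumor/non-tumor cohort for fast pipeline tests
small_cohort <- function(seed = 1, ...) {
  cfg <- syntheticConfig(n_tumor = 60L, n_non_tumor = 20L,
                         n_genes_total = 300L, n_matrisome = 200L,
                         n_signature = 10L,
                         block_spec = list(c(20, 0.7), c(15, 0.5)),
                         seed = seed, ...)
  simulateBulkCohort(cfg)
}
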