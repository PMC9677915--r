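## Single-sample scores: rank-based gene-set enrichment (weighted KS
## running sum), combined-z set scores, the +/-1-weighted fibrosis score,
## and per-cell module scores with expression-matched control genes.

## Weighted KS running-sum enrichment of one set in one sample.
## ranks: per-gene rank values (higher expression -> higher rank).
.ksRunningSum <- function(ranks, inSet, tau = 0.25) {
  ord <- order(ranks, decreasing = TRUE)
  inS <- inSet[ord]
  w <- abs(ranks[ord])^tau
  stepIn <- ifelse(inS, w, 0)
  denomIn <- sum(stepIn)
  stepOut <- ifelse(inS, 0, 1)
  denomOut <- sum(stepOut)
  sum(cumsum(stepIn) / denomIn - cumsum(stepOut) / denomOut)
}

#' Single-sample gene-set scores
#'
#' Scores each sample for each gene set. The default
#' \code{"rank_enrichment"} method ranks genes within each sample and
#' takes the weighted Kolmogorov-Smirnov running-sum statistic of the set
#' genes (rank weights raised to \code{tau = 0.25}) minus the non-set
#' running sum, then normalizes each set's scores by their range over
#' samples. \code{"weighted_z"} is the combined z-score
#' \code{sum(z_i)/sqrt(|set|)} on per-gene standardized expression;
#' \code{"module_score"} delegates to [moduleScore()].
#'
#' @param expr log2-unit expression container or matrix.
#' @param sets named list of gene sets ([readGMT()]); sets sharing fewer
#'   than 5 genes with the matrix are skipped with a warning.
#' @param method scoring method tag.
#' @param tau rank-weight exponent for \code{"rank_enrichment"}.
#' @param seed seed for \code{"module_score"} control-gene draws.
#' @return numeric matrix, sets x samples, with the method recorded in
#'   \code{attr(, "method")}.
#' @export
geneSetScore <- function(expr, sets,
                         method = c("rank_enrichment", "weighted_z",
                                    "module_score"),
                         tau = 0.25, seed = 1L) {
  method <- match.arg(method)
  m <- exprValues(expr)
  if (!length(sets)) stop("empty gene-set collection")
  shared <- lapply(sets, function(s) intersect(s, rownames(m)))
  usable <- vapply(shared, length, integer(1)) >= 5L
  if (!all(usable))
    warning("skipping ", sum(!usable),
            " set(s) sharing < 5 genes with the matrix: ",
            paste(names(sets)[!usable], collapse = ", "))
  if (!any(usable)) stop("no usable gene sets")
  shared <- shared[usable]
  scores <- switch(method,
    rank_enrichment = {
      ranks <- apply(m, 2L, rank, ties.method = "average")
      es <- vapply(shared, function(genes) {
        inSet <- rownames(m) %in% genes
        apply(ranks, 2L, .ksRunningSum, inSet = inSet, tau = tau)
      }, numeric(ncol(m)))
      es <- t(es)
      rng <- apply(es, 1L, function(x) diff(range(x)))
      sweep(es, 1L, ifelse(rng > 0, rng, 1), `/`)
    },
    weighted_z = {
      z <- .zmat(zscaleGenes(ExpressionMatrix(m, unit = "log2")))
      t(vapply(shared, function(genes) {
        genes <- intersect(genes, rownames(z))
        colSums(z[genes, , drop = FALSE]) / sqrt(length(genes))
      }, numeric(ncol(m))))
    },
    module_score = {
      t(vapply(shared, function(genes)
        moduleScore(m, genes, seed = seed), numeric(ncol(m))))
    })
  dimnames(scores) <- list(names(shared), colnames(m))
  attr(scores, "method") <- method
  scores
}

#' Fibrosis score from a +/-1-weighted signature
#'
#' Per-sample sum of signed z-scaled expression,
#' \code{score(s) = sum_i w_i z_i(s)}, over the signature genes present in
#' the matrix (w = +1 for genes up in fibrotic lung, -1 for genes down).
#' Missing signature genes are counted and reported via an attribute.
#'
#' @param z [ZScaledMatrix-class] or genes x samples matrix.
#' @param signature data.frame with columns gene, weight
#'   ([readFibrosisSignature()]).
#' @return Named numeric vector of per-sample scores;
#'   \code{attr(, "n_missing")} gives the number of absent signature genes.
#' @export
fibrosisScore <- function(z, signature) {
  m <- .zmat(z)
  present <- signature$gene %in% rownames(m)
  if (!any(present))
    stop("no fibrosis signature gene present in the matrix")
  sig <- signature[present, , drop = FALSE]
  s <- drop(colSums(m[sig$gene, , drop = FALSE] * sig$weight))
  attr(s, "n_missing") <- sum(!present)
  s
}

#' Per-cell module score with expression-matched controls
#'
#' Mean expression of the set genes minus the mean of control genes
#' matched on average expression: genes are binned into \code{n_bins} by
#' their mean expression over cells, and for each set gene
#' \code{n_control} control genes (capped at the bin size) are drawn from
#' its bin. Deterministic given the seed.
#'
#' @param cells log2-unit expression container or matrix with cells as
#'   columns.
#' @param set character vector of set genes (all must be present).
#' @param n_bins expression bins (default 24).
#' @param n_control controls per set gene (default 100).
#' @param seed integer seed.
#' @return Named numeric vector of per-cell scores.
#' @export
moduleScore <- function(cells, set, n_bins = 24L, n_control = 100L,
                        seed = 1L) {
  m <- exprValues(cells)
  if (length(set) >= nrow(m))
    stop("gene set is as large as the matrix; no control genes available")
  missing <- setdiff(set, rownames(m))
  if (length(missing))
    stop("set gene(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  avg <- rowMeans(m)
  nBins <- min(n_bins, nrow(m))
  bin <- cut(rank(avg, ties.method = "first"), breaks = nBins,
             labels = FALSE)
  names(bin) <- rownames(m)
  set.seed(seed)
  controls <- unlist(lapply(set, function(g) {
    pool <- setdiff(names(bin)[bin == bin[g]], g)
    if (!length(pool)) return(character(0))
    sample(pool, min(n_control, length(pool)))
  }))
  if (!length(controls))
    stop("no control genes available; reduce n_bins or the set size")
  colMeans(m[set, , drop = FALSE]) - colMeans(m[controls, , drop = FALSE])
}
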