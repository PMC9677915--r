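## Differential expression of (matrisome) genes between tumor and
## non-tumor tissue, and discovery of correlated core-matrisome clusters.
## The two-group moderated test goes through limma's empirical-Bayes
## machinery; setting prior_df = 0 reduces it to the ordinary pooled-
## variance two-sample t-test.

#' Moderated two-group differential expression
#'
#' Fits a per-gene two-group linear model (tumor vs non-tumor), shrinks the
#' gene-wise variances toward a pooled prior by empirical-Bayes moderation
#' and reports moderated t-statistics, raw and BH-adjusted p-values.
#' \code{logFC} is the mean difference \code{tumor - non_tumor} on the log2
#' scale. Genes that are identical in both classes get \code{logFC = 0, t =
#' 0, p = 1}.
#'
#' @param expr log2-unit expression container or matrix.
#' @param classes per-sample labels aligned with the columns; exactly two
#'   levels, each with >= 2 samples. For tumor/non-tumor data use
#'   \code{"tumor"}/\code{"non_tumor"}; \code{logFC} is level 2 minus level
#'   1 of \code{sort(unique(classes))} unless classes is a factor, whose
#'   level order is respected.
#' @param alpha BH significance level for the \code{significant} flag.
#' @param prior_df \code{NULL} (default) estimates the empirical-Bayes
#'   prior from the variance distribution; \code{0} disables moderation and
#'   yields ordinary two-sample t-tests.
#' @param annotation optional matrisome annotation
#'   ([readMatrisomeAnnotation()]) joined onto the result.
#' @return data.frame with columns gene, logFC, t, p_value, adj_p_value,
#'   significant (and division/category when annotated), ordered by p.
#' @export
differentialExpression <- function(expr, classes, alpha = 0.05,
                                   prior_df = NULL, annotation = NULL) {
  m <- exprValues(expr)
  .checkUnit(expr, "log2")
  tab <- .moderatedTwoGroup(m, classes, alpha = alpha, prior_df = prior_df)
  if (!is.null(annotation)) {
    i <- match(tab$gene, annotation$gene)
    tab$division <- annotation$division[i]
    tab$category <- annotation$category[i]
  }
  tab
}

## Core moderated two-group test shared with the ligand-receptor module.
.moderatedTwoGroup <- function(m, classes, alpha = 0.05, prior_df = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  classes <- if (is.factor(classes)) droplevels(classes) else
    factor(classes, levels = sort(unique(as.character(classes))))
  if (length(classes) != ncol(m))
    stop("classes must align with the samples")
  if (nlevels(classes) != 2L)
    stop("exactly two classes are required")
  if (any(table(classes) < 2L))
    stop("both classes need >= 2 samples")
  design <- cbind(intercept = 1, group = as.numeric(classes) - 1)
  fit <- limma::lmFit(m, design)
  if (!is.null(prior_df) && prior_df == 0) {
    se <- fit$stdev.unscaled[, "group"] * fit$sigma
    logFC <- fit$coefficients[, "group"]
    t <- ifelse(se == 0, ifelse(logFC == 0, 0, sign(logFC) * Inf),
                logFC / se)
    p <- 2 * pt(-abs(t), df = fit$df.residual)
    p[se == 0 & logFC == 0] <- 1
    tab <- data.frame(gene = rownames(m), logFC = unname(logFC),
                      t = unname(t), p_value = unname(p))
  } else {
    eb <- limma::eBayes(fit)
    tab <- data.frame(gene = rownames(m),
                      logFC = unname(eb$coefficients[, "group"]),
                      t = unname(eb$t[, "group"]),
                      p_value = unname(eb$p.value[, "group"]))
    flat <- fit$sigma == 0 & tab$logFC == 0
    tab$t[flat] <- 0
    tab$p_value[flat] <- 1
  }
  tab$adj_p_value <- p.adjust(tab$p_value, method = "BH")
  tab$significant <- tab$adj_p_value < alpha
  tab <- tab[order(tab$p_value, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "contrast") <- paste(levels(classes)[2], "-", levels(classes)[1])
  attr(tab, "alpha") <- alpha
  tab
}

#' Correlated gene clusters from Spearman correlation
#'
#' Computes pairwise Spearman correlations over the supplied samples
#' (typically tumor samples only, restricted to significant core-matrisome
#' genes), BH-adjusts two-sided correlation p-values over the upper
#' triangle, and cuts an average-linkage hierarchical clustering of the
#' distance \code{1 - rho} at \code{k} clusters.
#'
#' @param expr log2-unit expression container or matrix (genes x samples).
#' @param k number of clusters (>= 2).
#' @return A [CorrelationClustering-class].
#' @export
correlationClusters <- function(expr, k = 4L) {
  m <- exprValues(expr)
  if (k < 2L) stop("k must be >= 2")
  if (ncol(m) < 5L) stop("correlation clustering needs >= 5 samples")
  sdv <- apply(m, 1L, sd)
  dropped <- rownames(m)[sdv == 0]
  if (length(dropped)) {
    warning("excluding ", length(dropped), " constant gene(s)")
    m <- m[sdv > 0, , drop = FALSE]
  }
  if (nrow(m) < k) stop("need at least k genes after filtering")
  rho <- cor(t(m), method = "spearman")
  n <- ncol(m)
  ## two-sided asymptotic t-approximation for Spearman's rho
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  up <- upper.tri(p)
  padj <- p
  padj[up] <- p.adjust(p[up], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  hc <- hclust(as.dist(1 - rho), method = "average")
  labels <- cutree(hc, k = min(k, nrow(m)))
  new("CorrelationClustering", rho = rho, padj = padj,
      labels = setNames(as.integer(labels), rownames(m)),
      linkage = "average linkage on 1 - Spearman rho",
      droppedGenes = dropped)
}
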