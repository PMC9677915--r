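## Count filtering, TMM normalization, log2 transform and per-gene
## standardization. TMM goes through edgeR (trim fractions 0.3 on M-values
## and 0.05 on A-values, precision weights, reference sample chosen by the
## 75th-percentile rule); the log2-CPM transform uses effective library
## sizes with a CPM offset of 0.5 to avoid -Inf.

#' Filter, TMM-normalize and log2-transform a count matrix
#'
#' Keeps genes with \code{count >= min_count} in at least \code{min_prop}
#' of samples, computes TMM scaling factors against a reference sample
#' (the sample whose upper-quartile is closest to the mean upper-quartile),
#' and returns \code{log2(CPM + 0.5)} on effective library sizes
#' (library size x TMM factor).
#'
#' @param counts count-unit expression container or matrix
#'   (see [ExpressionMatrix()]); at least 2 samples.
#' @param min_count,min_prop filtering thresholds (defaults 10 and 0.2).
#' @return A log2-unit \code{SummarizedExperiment} with the TMM factors in
#'   \code{metadata(x)$tmm_factors} and effective library sizes in
#'   \code{metadata(x)$effective_lib_sizes}; \code{colData} is carried over.
#' @export
tmmNormalizeLog2 <- function(counts, min_count = 10, min_prop = 0.2) {
  .checkUnit(counts, "counts")
  m <- exprValues(counts)
  if (ncol(m) < 2L) stop("TMM normalization needs >= 2 samples")
  libSize <- colSums(m)
  if (any(libSize == 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[libSize == 0], collapse = ", "))
  keep <- rowMeans(m >= min_count) >= min_prop
  if (!any(keep)) stop("all genes removed by the count filter")
  f <- m[keep, , drop = FALSE]
  dge <- edgeR::DGEList(counts = f)
  dge <- edgeR::calcNormFactors(dge, method = "TMM",
                                logratioTrim = 0.3, sumTrim = 0.05,
                                doWeighting = TRUE)
  factors <- setNames(dge$samples$norm.factors, colnames(f))
  effLib <- libSize[colnames(f)] * factors
  cpm <- sweep(f, 2, effLib / 1e6, `/`)
  logExpr <- log2(cpm + 0.5)
  cd <- if (is(counts, "SummarizedExperiment"))
    SummarizedExperiment::colData(counts) else NULL
  out <- ExpressionMatrix(logExpr, unit = "log2", colData = cd)
  S4Vectors::metadata(out)$tmm_factors <- factors
  S4Vectors::metadata(out)$effective_lib_sizes <- effLib
  S4Vectors::metadata(out)$filtered_genes <- rownames(m)[!keep]
  out
}

#' Per-gene z-scaling of log2 expression
#'
#' Standardizes each gene to mean 0 and SD 1 over the scaling cohort. With
#' a \code{reference} (a previously fitted [ZScaledMatrix-class] or the
#' output of [readZScaleModel()]), the reference's stored means and SDs are
#' applied instead, projecting external samples onto the reference scale.
#' Zero-variance genes are dropped with a warning and recorded.
#'
#' @param expr log2-unit expression container or matrix.
#' @param reference optional [ZScaledMatrix-class] supplying means/SDs.
#' @param cohort provenance tag stored with the result.
#' @return A [ZScaledMatrix-class].
#' @export
zscaleGenes <- function(expr, reference = NULL, cohort = "cohort") {
  .checkUnit(expr, "log2")
  m <- exprValues(expr)
  if (is.null(reference)) {
    if (ncol(m) < 2L)
      stop("z-scaling without a reference needs >= 2 samples")
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, sd)
    drop <- sdv == 0 | !is.finite(sdv)
  } else {
    stopifnot(is(reference, "ZScaledMatrix"))
    shared <- intersect(rownames(m), names(reference@geneMeans))
    if (!length(shared))
      stop("no genes shared with the reference scaling model")
    m <- m[shared, , drop = FALSE]
    mu <- reference@geneMeans[shared]
    sdv <- reference@geneSds[shared]
    drop <- sdv <= 0 | !is.finite(sdv)
  }
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance gene(s): ",
            paste(head(rownames(m)[drop], 10L), collapse = ", "),
            if (sum(drop) > 10L) ", ..." else "")
  }
  kept <- !drop
  z <- (m[kept, , drop = FALSE] - mu[kept]) / sdv[kept]
  new("ZScaledMatrix", z = z,
      geneMeans = setNames(unname(mu[kept]), rownames(m)[kept]),
      geneSds = setNames(unname(sdv[kept]), rownames(m)[kept]),
      droppedGenes = rownames(m)[drop], cohort = cohort)
}
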