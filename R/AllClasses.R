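#' @import methods
#' @importFrom stats sd cor cov p.adjust pt pchisq rnorm rnbinom rpois rexp
#'   runif kmeans hclust cutree as.dist setNames fisher.test wilcox.test
#'   complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

#' ZScaledMatrix: per-gene standardized expression
#'
#' Container for a gene x sample matrix of per-gene standardized (z-scaled)
#' log2 expression together with the per-gene means and standard deviations
#' used for scaling, so that external samples can later be projected onto the
#' same scale. Genes with zero variance in the scaling cohort are excluded
#' and recorded in \code{droppedGenes}.
#'
#' @slot z numeric matrix (genes x samples) of z-scaled expression.
#' @slot geneMeans named numeric vector of per-gene means on the log2 scale.
#' @slot geneSds named numeric vector of per-gene standard deviations.
#' @slot droppedGenes character vector of zero-variance genes excluded.
#' @slot cohort single string tagging the scaling cohort.
#'
#' @seealso [zscaleGenes()]
#' @export
setClass("ZScaledMatrix",
  representation(
    z = "matrix",
    geneMeans = "numeric",
    geneSds = "numeric",
    droppedGenes = "character",
    cohort = "character"
  )
)

setValidity("ZScaledMatrix", function(object) {
  msg <- NULL
  z <- object@z
  if (is.null(rownames(z)) || (ncol(z) > 0 && is.null(colnames(z))))
    msg <- c(msg, "z matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(z)) || anyDuplicated(colnames(z)))
    msg <- c(msg, "duplicate gene or sample identifiers")
  if (!identical(names(object@geneMeans), rownames(z)) ||
      !identical(names(object@geneSds), rownames(z)))
    msg <- c(msg, "geneMeans/geneSds must be named by the genes of z")
  if (any(!is.finite(z)))
    msg <- c(msg, "z values must be finite")
  if (any(object@geneSds <= 0))
    msg <- c(msg, "stored gene SDs must be positive")
  if (length(object@cohort) != 1L)
    msg <- c(msg, "cohort must be a single string")
  if (is.null(msg)) TRUE else msg
})

#' RiskSignature: weighted matrisome gene signature
#'
#' A matrix risk signature: an ordered set of genes with log(odds ratio)
#' weights from Firth-penalized logistic regression. The per-sample matrix
#' risk score is the weighted sum of z-scaled expression over the signature
#' (see [matrixRiskScore()]).
#'
#' @slot genes character vector of unique gene symbols.
#' @slot beta named numeric vector of log odds-ratio weights, one per gene.
#' @slot provenance list recording how the signature was fit (cohort,
#'   lambda, alpha, partition seed, fitting mode).
#'
#' @export
setClass("RiskSignature",
  representation(genes = "character", beta = "numeric", provenance = "list")
)

setValidity("RiskSignature", function(object) {
  msg <- NULL
  if (length(object@genes) < 1L) msg <- c(msg, "signature must contain >= 1 gene")
  if (anyDuplicated(object@genes)) msg <- c(msg, "signature genes must be unique")
  if (!identical(names(object@beta), object@genes))
    msg <- c(msg, "beta must be named by the signature genes, in order")
  if (any(!is.finite(object@beta))) msg <- c(msg, "all weights must be finite")
  if (is.null(msg)) TRUE else msg
})

#' ConsensusResult: Monte-Carlo consensus clustering output
#'
#' Result of Monte-Carlo reference-based consensus clustering over a range
#' of cluster numbers K: per-K consensus matrices, PAC scores, null PAC
#' distributions from reference datasets, RCSI values, Monte-Carlo p-values,
#' the chosen K and the final sample labels.
#'
#' @slot kRange integer vector of candidate cluster numbers.
#' @slot consensus named list of per-K sample x sample consensus matrices.
#' @slot pac numeric vector of per-K PAC scores (proportion of ambiguous
#'   clustering).
#' @slot nullPac named list of per-K null PAC vectors (one per Monte-Carlo
#'   reference dataset).
#' @slot rcsi numeric vector of per-K relative cluster stability indices,
#'   computed as log(mean null PAC) - log(real PAC) with a 1e-6 floor on
#'   PAC values before logs.
#' @slot mcP numeric vector of per-K Monte-Carlo p-values.
#' @slot chosenK integer; NA when no K reaches Monte-Carlo significance.
#' @slot labels named integer vector of final cluster labels (empty when no
#'   significant structure was found).
#'
#' @export
setClass("ConsensusResult",
  representation(
    kRange = "integer", consensus = "list", pac = "numeric",
    nullPac = "list", rcsi = "numeric", mcP = "numeric",
    chosenK = "integer", labels = "integer"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- NULL
  nk <- length(object@kRange)
  if (length(object@pac) != nk || length(object@rcsi) != nk ||
      length(object@mcP) != nk || length(object@consensus) != nk)
    msg <- c(msg, "per-K slots must align with kRange")
  for (cm in object@consensus) {
    if (!isSymmetric(unname(cm), tol = 1e-8) ||
        any(cm < -1e-12 | cm > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "consensus matrices must be symmetric with entries in [0,1]")
  }
  if (any(object@pac < 0 | object@pac > 1))
    msg <- c(msg, "PAC must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' CentroidModel: per-cluster mean expression profiles
#'
#' Mean z-scaled expression per cluster label over a fixed gene panel; used
#' to assign new samples to matreotypes by minimum Euclidean distance
#' ([centroidAssign()]).
#'
#' @slot centroids numeric matrix, genes x labels.
#'
#' @export
setClass("CentroidModel", representation(centroids = "matrix"))

setValidity("CentroidModel", function(object) {
  msg <- NULL
  cm <- object@centroids
  if (is.null(rownames(cm)) || is.null(colnames(cm)))
    msg <- c(msg, "centroid matrix needs gene rownames and label colnames")
  if (anyDuplicated(colnames(cm))) msg <- c(msg, "labels must be unique")
  if (anyDuplicated(rownames(cm))) msg <- c(msg, "genes must be unique")
  if (is.null(msg)) TRUE else msg
})

#' CorrelationClustering: correlated gene modules
#'
#' Pairwise Spearman correlation structure of a gene panel with BH-adjusted
#' correlation p-values and average-linkage hierarchical cluster labels on
#' the distance 1 - rho.
#'
#' @slot rho symmetric Spearman correlation matrix.
#' @slot padj symmetric matrix of BH-adjusted two-sided correlation
#'   p-values (adjusted over the upper triangle).
#' @slot labels named integer cluster label per gene.
#' @slot linkage single string describing the linkage used.
#' @slot droppedGenes constant genes excluded before correlation.
#'
#' @export
setClass("CorrelationClustering",
  representation(
    rho = "matrix", padj = "matrix", labels = "integer",
    linkage = "character", droppedGenes = "character"
  )
)

setValidity("CorrelationClustering", function(object) {
  msg <- NULL
  if (!isSymmetric(unname(object@rho), tol = 1e-8))
    msg <- c(msg, "rho must be symmetric")
  if (any(abs(object@rho) > 1 + 1e-12))
    msg <- c(msg, "|rho| must be <= 1")
  if (!all(abs(diag(object@rho) - 1) < 1e-8))
    msg <- c(msg, "rho must have unit diagonal")
  if (!identical(names(object@labels), rownames(object@rho)))
    msg <- c(msg, "labels must cover exactly the clustered genes")
  if (is.null(msg)) TRUE else msg
})

#' InteractionScoreMatrix: ligand-receptor interaction scores
#'
#' Per-pair, per-sample interaction scores: the product of the z-scaled
#' receptor and ligand expression in each sample. Pairs with either gene
#' absent from the expression matrix are dropped and recorded.
#'
#' @slot scores numeric matrix, pairs x samples; rownames are
#'   "LIGAND_RECEPTOR" strings.
#' @slot pairs data.frame with columns ligand, receptor, receptor_class,
#'   pathways (list-free, semicolon-delimited string), aligned with the rows
#'   of \code{scores}.
#' @slot dropped data.frame of pairs excluded for missing genes.
#'
#' @export
setClass("InteractionScoreMatrix",
  representation(scores = "matrix", pairs = "data.frame", dropped = "data.frame")
)

setValidity("InteractionScoreMatrix", function(object) {
  msg <- NULL
  if (nrow(object@scores) != nrow(object@pairs))
    msg <- c(msg, "pairs table must align with score rows")
  if (is.null(msg)) TRUE else msg
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ZScaledMatrix", function(object) {
  cat("ZScaledMatrix:", nrow(object@z), "genes x", ncol(object@z),
      "samples (cohort:", object@cohort, ")\n")
  if (length(object@droppedGenes))
    cat("  zero-variance genes dropped:", length(object@droppedGenes), "\n")
})

setMethod("show", "RiskSignature", function(object) {
  cat("RiskSignature with", length(object@genes), "genes\n")
  n <- min(5L, length(object@genes))
  cat("  top weights:",
      paste(sprintf("%s=%.3f", object@genes[seq_len(n)],
                    object@beta[seq_len(n)]), collapse = ", "), "\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over K =", paste(object@kRange, collapse = ","), "\n")
  if (is.na(object@chosenK)) {
    cat("  no significant cluster structure (all Monte-Carlo p >= 0.05)\n")
  } else {
    cat(sprintf("  chosen K = %d (PAC %.3f, RCSI %.3f, MC p %.3g)\n",
                object@chosenK,
                object@pac[match(object@chosenK, object@kRange)],
                object@rcsi[match(object@chosenK, object@kRange)],
                object@mcP[match(object@chosenK, object@kRange)]))
  }
})

setMethod("show", "CentroidModel", function(object) {
  cat("CentroidModel:", ncol(object@centroids), "centroids over",
      nrow(object@centroids), "genes (",
      paste(colnames(object@centroids), collapse = ", "), ")\n")
})

setMethod("show", "CorrelationClustering", function(object) {
  cat("CorrelationClustering:", nrow(object@rho), "genes in",
      length(unique(object@labels)), "clusters (", object@linkage, ")\n")
})

setMethod("show", "InteractionScoreMatrix", function(object) {
  cat("InteractionScoreMatrix:", nrow(object@scores), "ligand-receptor pairs x",
      ncol(object@scores), "samples\n")
  if (nrow(object@dropped))
    cat("  pairs dropped (missing genes):", nrow(object@dropped), "\n")
})

## ---- accessors ----------------------------------------------------------

#' Accessors for matreotypes S4 objects
#'
#' Small accessor family: \code{zValues} returns the z-scaled matrix,
#' \code{geneMeans}/\code{geneSds} the stored scaling parameters,
#' \code{signatureGenes}/\code{signatureWeights} the genes and log-odds
#' weights of a [RiskSignature-class], \code{chosenK} and
#' \code{clusterLabels} the selected cluster number and labels of a
#' [ConsensusResult-class], \code{consensusMatrix} the consensus matrix at a
#' given K, \code{centroidMatrix} the gene x label centroid matrix, and
#' \code{interactionMatrix}/\code{pairInfo} the score matrix and pair table
#' of an [InteractionScoreMatrix-class].
#'
#' @param x an object of the documented classes.
#' @param k cluster number at which to extract a consensus matrix.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
#' @rdname accessors
#' @export
setMethod("zValues", "ZScaledMatrix", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("geneMeans", function(x) standardGeneric("geneMeans"))
#' @rdname accessors
#' @export
setMethod("geneMeans", "ZScaledMatrix", function(x) x@geneMeans)

#' @rdname accessors
#' @export
setGeneric("geneSds", function(x) standardGeneric("geneSds"))
#' @rdname accessors
#' @export
setMethod("geneSds", "ZScaledMatrix", function(x) x@geneSds)

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))
#' @rdname accessors
#' @export
setMethod("signatureGenes", "RiskSignature", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("signatureWeights", function(x) standardGeneric("signatureWeights"))
#' @rdname accessors
#' @export
setMethod("signatureWeights", "RiskSignature", function(x) x@beta)

#' @rdname accessors
#' @export
setGeneric("chosenK", function(x) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setMethod("chosenK", "ConsensusResult", function(x) x@chosenK)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "CorrelationClustering", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x, k) standardGeneric("consensusMatrix"))
#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k) {
  i <- match(as.integer(k), x@kRange)
  if (is.na(i)) stop("K = ", k, " not in the fitted range")
  x@consensus[[i]]
})

#' @rdname accessors
#' @export
setGeneric("centroidMatrix", function(x) standardGeneric("centroidMatrix"))
#' @rdname accessors
#' @export
setMethod("centroidMatrix", "CentroidModel", function(x) x@centroids)

#' @rdname accessors
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))
#' @rdname accessors
#' @export
setMethod("interactionMatrix", "InteractionScoreMatrix", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("pairInfo", function(x) standardGeneric("pairInfo"))
#' @rdname accessors
#' @export
setMethod("pairInfo", "InteractionScoreMatrix", function(x) x@pairs)
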