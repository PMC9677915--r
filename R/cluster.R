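## Matreotype discovery: Monte-Carlo reference-based consensus clustering
## with PAC/RCSI model selection, centroid construction, nearest-centroid
## assignment, and canonical molecular subtype classification by Pearson
## nearest-centroid.

#' Proportion of ambiguous clustering (PAC)
#'
#' Fraction of upper-triangle consensus entries strictly inside the
#' ambiguity window (default (0.1, 0.9)). Low PAC indicates a stable
#' clustering: most sample pairs either always or never co-cluster.
#'
#' @param consensus symmetric sample x sample consensus matrix with
#'   entries in [0, 1].
#' @param window numeric pair (lo, hi), lo < hi.
#' @return PAC in [0, 1].
#' @export
pacScore <- function(consensus, window = c(0.1, 0.9)) {
  if (window[1] >= window[2]) stop("window.lo must be < window.hi")
  up <- consensus[upper.tri(consensus)]
  if (!length(up)) return(0)
  mean(up > window[1] & up < window[2])
}

## One consensus matrix: `resamples` K-means runs on random column
## subsamples; entry (i,j) = co-cluster count / co-subsample count.
.consensusMatrix <- function(X, K, resamples, frac, nstart = 25L,
                             maxRetries = 10L) {
  n <- ncol(X)
  nSub <- max(round(frac * n), K + 1L)
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  for (r in seq_len(resamples)) {
    km <- NULL
    for (try in seq_len(maxRetries)) {
      idx <- sample.int(n, nSub)
      km <- tryCatch(
        kmeans(t(X[, idx, drop = FALSE]), centers = K, nstart = nstart,
               iter.max = 100L),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km))
      stop("resampling failed repeatedly (K = ", K,
           "): subsamples cannot support K clusters")
    eq <- outer(km$cluster, km$cluster, `==`)
    co[idx, idx] <- co[idx, idx] + eq
    tog[idx, idx] <- tog[idx, idx] + 1
  }
  cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
  diag(cons) <- 1
  dimnames(cons) <- list(colnames(X), colnames(X))
  cons
}

## Null reference preserving the gene covariance eigenstructure: draws
## from N(gene means, Sigma-hat) via the eigen-decomposition of the gene
## covariance (negative eigenvalues clipped at zero).
.nullDataset <- function(X, eig, mu) {
  A <- eig$vectors %*% diag(sqrt(pmax(eig$values, 0)), nrow(X))
  mu + A %*% matrix(rnorm(nrow(X) * ncol(X)), nrow(X), ncol(X))
}

#' Monte-Carlo reference-based consensus clustering
#'
#' For each candidate cluster number K, builds a consensus matrix from
#' repeated K-means runs on random sample subsets and summarizes its
#' stability by the PAC score. Significance of the observed stability is
#' assessed against \code{mc_iters} Monte-Carlo reference datasets drawn
#' multivariate-normal with the real data's per-gene means and gene
#' covariance eigenstructure (or by column-wise permutation with
#' \code{null_method = "permute"}), each processed identically. The
#' relative cluster stability index is \code{RCSI(K) = log(mean null PAC) -
#' log(real PAC)} (PAC floored at 1e-6 before logs) and the Monte-Carlo
#' p-value is \code{(1 + #\{null PAC <= real PAC\}) / (mc_iters + 1)}. The
#' chosen K maximizes RCSI among K with p < 0.05; when none is significant
#' the result reports no significant structure. Final labels come from
#' K-means on the full data at the chosen K with 25 restarts.
#'
#' @param z [ZScaledMatrix-class] or genes x samples matrix (typically DE
#'   core-matrisome genes; tumor and non-tumor samples together).
#' @param k_range candidate cluster numbers (default 2:10).
#' @param resamples K-means subsampling runs per K (default 100).
#' @param subsample_frac fraction of samples per run (default 0.8).
#' @param mc_iters Monte-Carlo reference datasets (default 25).
#' @param seed integer seed.
#' @param null_method \code{"eigen"} (covariance-preserving, default) or
#'   \code{"permute"}.
#' @param nstart K-means restarts per run (default 25).
#' @return A [ConsensusResult-class].
#' @export
consensusCluster <- function(z, k_range = 2:10, resamples = 100L,
                             subsample_frac = 0.8, mc_iters = 25L,
                             seed = 1L, null_method = c("eigen", "permute"),
                             nstart = 25L) {
  null_method <- match.arg(null_method)
  X <- .zmat(z)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("cluster numbers must be >= 2")
  if (ncol(X) < max(k_range) * 3L)
    stop("need at least 3 x max(k_range) samples")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must lie in (0, 1]")
  set.seed(seed)
  realCons <- lapply(k_range, function(K)
    .consensusMatrix(X, K, resamples, subsample_frac, nstart))
  realPac <- vapply(realCons, pacScore, numeric(1))
  mu <- rowMeans(X)
  eig <- if (null_method == "eigen") eigen(cov(t(X)), symmetric = TRUE)
  nullPac <- matrix(NA_real_, mc_iters, length(k_range))
  for (b in seq_len(mc_iters)) {
    Xnull <- if (null_method == "eigen") .nullDataset(X, eig, mu)
      else apply(X, 1L, sample) |> t()
    colnames(Xnull) <- colnames(X)
    nullPac[b, ] <- vapply(k_range, function(K)
      pacScore(.consensusMatrix(Xnull, K, resamples, subsample_frac, nstart)),
      numeric(1))
  }
  eps <- 1e-6
  rcsi <- log(pmax(colMeans(nullPac), eps)) - log(pmax(realPac, eps))
  mcP <- (1 + colSums(nullPac <= matrix(realPac, mc_iters,
                                        length(k_range), byrow = TRUE))) /
    (mc_iters + 1)
  sig <- which(mcP < 0.05)
  if (!length(sig)) {
    message("no significant cluster structure (all Monte-Carlo p >= 0.05)")
    chosen <- NA_integer_
    labels <- integer(0)
  } else {
    chosen <- k_range[sig[which.max(rcsi[sig])]]
    km <- kmeans(t(X), centers = chosen, nstart = 25L, iter.max = 100L)
    labels <- setNames(as.integer(km$cluster), colnames(X))
  }
  names(realCons) <- names(realPac) <- names(rcsi) <- names(mcP) <-
    paste0("K", k_range)
  new("ConsensusResult", kRange = k_range, consensus = realCons,
      pac = realPac, nullPac = lapply(seq_along(k_range), function(i)
        nullPac[, i]) |> setNames(paste0("K", k_range)),
      rcsi = rcsi, mcP = mcP, chosenK = chosen, labels = labels)
}

#' Build matreotype centroids from labelled samples
#'
#' Per-label mean of each gene over the labelled samples.
#'
#' @param z [ZScaledMatrix-class] or genes x samples matrix.
#' @param labels per-sample cluster/matreotype labels (named or aligned
#'   with columns).
#' @return A [CentroidModel-class].
#' @export
buildCentroids <- function(z, labels) {
  m <- .zmat(z)
  labels <- as.character(labels)
  if (length(labels) != ncol(m)) stop("labels must align with the samples")
  cents <- vapply(sort(unique(labels)), function(l)
    rowMeans(m[, labels == l, drop = FALSE]), numeric(nrow(m)))
  new("CentroidModel", centroids = cents)
}

#' Assign samples to the nearest centroid
#'
#' Assigns each sample the label of the Euclidean-nearest centroid over
#' the model genes. \code{model} may be a fitted [CentroidModel-class] or a
#' label vector, in which case centroids are first built from \code{z}
#' itself ([buildCentroids()]) and the samples then self-assigned.
#' Distance ties go to the first label in sorted order.
#'
#' @param z [ZScaledMatrix-class] or genes x samples matrix.
#' @param model [CentroidModel-class] or per-sample labels.
#' @return Named character vector of assigned labels, with the distance
#'   matrix in \code{attr(, "distance")}.
#' @export
centroidAssign <- function(z, model) {
  if (!is(model, "CentroidModel")) model <- buildCentroids(z, model)
  m <- .zmat(z)
  genes <- rownames(model@centroids)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("model gene(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  m <- m[genes, , drop = FALSE]
  d2 <- vapply(colnames(model@centroids), function(l)
    colSums((m - model@centroids[, l])^2), numeric(ncol(m)))
  d2 <- matrix(d2, ncol(m), ncol(model@centroids),
               dimnames = list(colnames(m), colnames(model@centroids)))
  ## ties resolved toward the first label in (sorted) column order
  labels <- colnames(d2)[apply(d2, 1L, which.min)]
  structure(setNames(labels, colnames(m)), distance = sqrt(d2))
}

#' Classify canonical molecular subtypes by Pearson nearest-centroid
#'
#' Correlates each sample with each published subtype centroid over the
#' shared genes and assigns the subtype with the highest Pearson
#' correlation. Samples whose best correlation is negative are flagged
#' low-confidence.
#'
#' @param expr log2-unit expression container or matrix.
#' @param centroids numeric matrix, genes x subtypes (a published centroid
#'   table); at least 10 genes must be shared with \code{expr}.
#' @return data.frame with sample, subtype, max_r, low_confidence and one
#'   correlation column per subtype.
#' @export
classifyCanonicalSubtype <- function(expr, centroids) {
  m <- exprValues(expr)
  centroids <- as.matrix(centroids)
  shared <- intersect(rownames(m), rownames(centroids))
  if (length(shared) < 10L)
    stop("fewer than 10 genes shared with the centroid table (",
         length(shared), ")")
  m <- m[shared, , drop = FALSE]
  centroids <- centroids[shared, , drop = FALSE]
  r <- cor(m, centroids, method = "pearson")
  best <- apply(r, 1L, which.max)
  out <- data.frame(sample = colnames(m),
                    subtype = colnames(centroids)[best],
                    max_r = r[cbind(seq_len(nrow(r)), best)],
                    low_confidence = r[cbind(seq_len(nrow(r)), best)] < 0,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(r))
}
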