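## Matrix risk signature: elastic-net gene selection, Firth-penalized
## log-odds weights, per-sample risk scores, ROC validation and minimal-
## signature refinement. The Firth fit is implemented here (Jeffreys-prior
## penalized likelihood, Newton iterations with step-halving); elastic-net
## selection goes through glmnet; ROC curves through pROC.

.zmat <- function(z) {
  if (is(z, "ZScaledMatrix")) z@z else as.matrix(z)
}

.binaryClasses <- function(classes, n, positive = NULL) {
  classes <- if (is.factor(classes)) droplevels(classes) else
    factor(classes, levels = sort(unique(as.character(classes))))
  if (length(classes) != n) stop("classes must align with the samples")
  if (nlevels(classes) != 2L) stop("exactly two classes are required")
  if (!is.null(positive)) {
    if (!positive %in% levels(classes)) stop("unknown positive class")
    classes <- stats::relevel(classes, ref = setdiff(levels(classes), positive))
  }
  classes
}

#' Stratified train/test partition
#'
#' Splits samples into training and test sets, stratified by tissue class,
#' deterministically for a given seed. Per class, \code{round(train_fraction
#' * n)} samples go to training.
#'
#' @param classes named character/factor vector of per-sample classes, or a
#'   metadata data.frame with \code{sample_id} and \code{tissue_class}.
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with character vectors \code{train} and \code{test}.
#' @export
partitionCohort <- function(classes, train_fraction = 0.8, seed = 1L) {
  if (is.data.frame(classes))
    classes <- setNames(classes$tissue_class, classes$sample_id)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (is.null(names(classes))) stop("classes must be named by sample id")
  if (any(table(classes) < 5L))
    stop("each class needs >= 5 samples to partition")
  set.seed(seed)
  train <- unlist(lapply(split(names(classes), as.character(classes)),
                         function(ids) {
                           nTrain <- round(train_fraction * length(ids))
                           sample(ids, nTrain)
                         }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(names(classes), train)))
}

.stratifiedFolds <- function(classes, folds, seed) {
  set.seed(seed)
  foldid <- integer(length(classes))
  for (cl in levels(classes)) {
    idx <- sample(which(classes == cl))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  foldid
}

#' Elastic-net gene selection for tumor vs non-tumor
#'
#' Penalized logistic regression over z-scaled candidate genes with penalty
#' \code{lambda * ((1 - alpha_mix)/2 * ||b||_2^2 + alpha_mix * ||b||_1)}.
#' The lambda path runs from lambda_max (smallest penalty zeroing all
#' coefficients) downward on a log grid; lambda is chosen by the one-
#' standard-error rule on the stratified cross-validated prediction error rate, falling back
#' to lambda_min (with a warning) when no gene survives at lambda_1se.
#'
#' @param z [ZScaledMatrix-class] (or plain genes x samples matrix) of the
#'   candidate genes, typically DE core-matrisome genes.
#' @param classes two-level per-sample labels.
#' @param alpha_mix elastic-net mixing parameter (0.5 default).
#' @param folds stratified CV folds (10 default).
#' @param seed seed for fold assignment.
#' @return list with \code{genes} (selected at the chosen lambda),
#'   \code{beta} (their coefficients), \code{lambda_min},
#'   \code{lambda_1se}, \code{lambda_used}, \code{cv} (lambda/error-rate
#'   curve) and the underlying \code{cv.glmnet} \code{fit}.
#' @export
elasticNetSelect <- function(z, classes, alpha_mix = 0.5, folds = 10L,
                             seed = 1L) {
  m <- .zmat(z)
  classes <- .binaryClasses(classes, ncol(m))
  if (min(table(classes)) < folds)
    stop("fewer samples than folds in a class; stratified folds impossible")
  foldid <- .stratifiedFolds(classes, folds, seed)
  x <- t(m)
  fit <- glmnet::cv.glmnet(x, classes, family = "binomial",
                           alpha = alpha_mix, foldid = foldid,
                           type.measure = "class",
                           standardize = FALSE, nlambda = 100,
                           lambda.min.ratio = 1e-4)
  pick <- function(s) {
    cf <- as.matrix(glmnet::coef.glmnet(fit, s = s))[-1, 1]
    names(cf)[cf != 0]
  }
  genes <- pick(fit$lambda.1se)
  lambdaUsed <- fit$lambda.1se
  if (!length(genes)) {
    warning("no gene selected at lambda_1se; falling back to lambda_min")
    genes <- pick(fit$lambda.min)
    lambdaUsed <- fit$lambda.min
  }
  cf <- as.matrix(glmnet::coef.glmnet(fit, s = lambdaUsed))[-1, 1]
  list(genes = genes, beta = cf[genes],
       lambda_min = fit$lambda.min, lambda_1se = fit$lambda.1se,
       lambda_used = lambdaUsed,
       cv = data.frame(lambda = fit$lambda, cvm = fit$cvm, cvsd = fit$cvsd),
       fit = fit)
}

## Firth-penalized logistic regression: maximizes log-likelihood +
## 0.5 * log det(X'WX). Newton steps on the modified score
## U* = X'(y - p + h (1/2 - p)), step-halving on the penalized likelihood.
.firthFit <- function(X, y, maxit = 200L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  penLoglik <- function(beta) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    W <- pmax(pr * (1 - pr), 1e-12)
    XtWX <- crossprod(X, X * W)
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    ll + 0.5 * as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
  }
  converged <- FALSE
  iter <- 0L
  gradNorm <- Inf
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    W <- pmax(pr * (1 - pr), 1e-12)
    XtWX <- crossprod(X, X * W)
    XtWXinv <- tryCatch(solve(XtWX), error = function(e)
      stop("numerical error: singular information matrix in Firth fit"))
    h <- W * rowSums((X %*% XtWXinv) * X)
    U <- drop(crossprod(X, y - pr + h * (0.5 - pr)))
    gradNorm <- max(abs(U))
    if (gradNorm < tol) { converged <- TRUE; break }
    delta <- drop(XtWXinv %*% U)
    ll0 <- penLoglik(beta)
    step <- 1
    repeat {
      cand <- beta + step * delta
      llc <- penLoglik(cand)
      if (is.finite(llc) && llc >= ll0 - 1e-9 * (abs(ll0) + 1)) break
      step <- step / 2
      if (step < 1e-10) break
    }
    ## a stationary step at floating-point resolution counts as converged
    if (max(abs(step * delta)) < 1e-10) { converged <- TRUE; break }
    beta <- beta + step * delta
  }
  if (!converged && gradNorm > 1e-4)
    stop("numerical error: Firth fit did not converge in ", maxit,
         " iterations (max |score| = ", format(gradNorm), ")")
  list(beta = beta, iterations = iter,
       vcov = solve(crossprod(X, X * pmax(stats::plogis(drop(X %*% beta)) *
                                            (1 - stats::plogis(drop(X %*% beta))),
                                          1e-12))))
}

#' Firth-corrected log odds ratios for a gene panel
#'
#' Fits logistic regression of class membership on z-scaled expression with
#' Firth's Jeffreys-prior penalty, which keeps estimates finite under
#' complete separation and reduces small-sample bias. \code{mode = "joint"}
#' (default) fits all genes in one model so each weight is adjusted for the
#' rest of the panel; \code{mode = "per_gene"} fits one single-gene model
#' per gene. Optional clinical covariates can be appended to the joint
#' model; covariate terms are recorded in the provenance but not part of
#' the signature weights.
#'
#' @param z [ZScaledMatrix-class] or genes x samples matrix restricted to
#'   the signature genes.
#' @param classes two-level per-sample labels; the positive class is the
#'   second sorted level (override with \code{positive}).
#' @param mode \code{"joint"} or \code{"per_gene"}.
#' @param positive optional label to treat as the positive (odds numerator)
#'   class.
#' @param covariates optional numeric matrix (samples x covariates)
#'   appended to the joint design.
#' @param genes optional subset of genes to use.
#' @return A [RiskSignature-class] with \code{beta} = log odds ratio per
#'   gene.
#' @export
firthLogOdds <- function(z, classes, mode = c("joint", "per_gene"),
                         positive = NULL, covariates = NULL, genes = NULL) {
  mode <- match.arg(mode)
  m <- .zmat(z)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stop("genes absent from the matrix: ", paste(missing, collapse = ", "))
    m <- m[genes, , drop = FALSE]
  }
  classes <- .binaryClasses(classes, ncol(m), positive = positive)
  if (any(table(classes) < 2L)) stop("both classes need >= 2 samples")
  y <- as.numeric(classes) - 1
  if (mode == "joint") {
    X <- cbind(`(Intercept)` = 1, t(m))
    if (!is.null(covariates)) {
      covariates <- as.matrix(covariates)
      stopifnot(nrow(covariates) == ncol(m))
      X <- cbind(X, covariates)
    }
    fit <- .firthFit(X, y)
    beta <- setNames(fit$beta[seq_len(nrow(m)) + 1L], rownames(m))
    cov_beta <- if (!is.null(covariates))
      setNames(fit$beta[-seq_len(nrow(m) + 1L)], colnames(X)[-seq_len(nrow(m) + 1L)])
    else NULL
  } else {
    beta <- vapply(rownames(m), function(g) {
      .firthFit(cbind(1, m[g, ]), y)$beta[2]
    }, numeric(1))
    cov_beta <- NULL
  }
  new("RiskSignature", genes = rownames(m), beta = beta,
      provenance = list(mode = mode, positive = levels(classes)[2],
                        n_samples = ncol(m), covariates = cov_beta))
}

#' Matrix risk score
#'
#' Per-sample weighted sum of z-scaled expression over the signature:
#' \code{score(s) = sum_i z_i(s) * beta_i}. Samples lacking signature genes
#' are an error, not imputed.
#'
#' @param z [ZScaledMatrix-class] or genes x samples matrix containing all
#'   signature genes.
#' @param signature a [RiskSignature-class].
#' @return Named numeric vector of per-sample scores.
#' @export
matrixRiskScore <- function(z, signature) {
  m <- .zmat(z)
  missing <- setdiff(signature@genes, rownames(m))
  if (length(missing))
    stop("signature gene(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  drop(colSums(m[signature@genes, , drop = FALSE] * signature@beta))
}

#' ROC curve and AUC for a score
#'
#' Computes the full ROC curve and the area under it for a numeric score
#' against two-level labels. The AUC equals the rank (Mann-Whitney)
#' statistic with ties counted one half.
#'
#' @param scores named numeric vector.
#' @param classes two-level labels aligned with the scores; positive class
#'   is the second sorted level unless \code{positive} is given.
#' @param positive optional positive-class label.
#' @return list with \code{auc} and \code{curve} (data.frame threshold,
#'   tpr, fpr ordered from the (0,0) to the (1,1) corner).
#' @export
rocAuc <- function(scores, classes, positive = NULL) {
  classes <- .binaryClasses(classes, length(scores), positive = positive)
  r <- pROC::roc(response = classes, predictor = as.numeric(scores),
                 levels = levels(classes), direction = "<", quiet = TRUE)
  ord <- order(1 - r$specificities, r$sensitivities)
  curve <- data.frame(threshold = r$thresholds[ord],
                      tpr = r$sensitivities[ord],
                      fpr = 1 - r$specificities[ord])
  list(auc = as.numeric(r$auc), curve = curve)
}

.cvAuc <- function(m, y, classes, folds, seed) {
  foldid <- .stratifiedFolds(classes, folds, seed)
  oof <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    X <- cbind(1, t(m[, tr, drop = FALSE]))
    fit <- .firthFit(X, y[tr])
    oof[!tr] <- drop(cbind(1, t(m[, !tr, drop = FALSE])) %*% fit$beta)
  }
  rocAuc(oof, classes)$auc
}

#' Refine a minimal risk signature
#'
#' Searches subsets of the signature genes of size up to \code{max_size},
#' refitting each subset with [firthLogOdds()] and scoring it by stratified
#' cross-validated AUC. The search is exhaustive when the number of
#' candidate subsets is at most 1e5 and greedy forward selection otherwise.
#' Ties in CV AUC are broken by smaller subset size, then lexicographic
#' gene order.
#'
#' @param z [ZScaledMatrix-class] or matrix containing the signature genes.
#' @param signature a [RiskSignature-class] whose genes form the search
#'   space.
#' @param classes two-level labels.
#' @param max_size largest subset size (>= 1).
#' @param folds,seed CV parameters.
#' @return data.frame with columns subset (comma-joined genes), size,
#'   cv_auc, ranked best-first.
#' @export
refineMinimalSignature <- function(z, signature, classes, max_size,
                                   folds = 5L, seed = 1L) {
  m <- .zmat(z)[signature@genes, , drop = FALSE]
  n <- nrow(m)
  if (max_size < 1L) stop("max_size must be >= 1")
  if (max_size > n) stop("max_size exceeds the signature size")
  classes <- .binaryClasses(classes, ncol(m))
  y <- as.numeric(classes) - 1
  nSubsets <- sum(choose(n, seq_len(max_size)))
  evalSubset <- function(genes) {
    .cvAuc(m[genes, , drop = FALSE], y, classes, folds, seed)
  }
  if (nSubsets <= 1e5) {
    subsets <- unlist(lapply(seq_len(max_size), function(k)
      combn(signature@genes, k, simplify = FALSE)), recursive = FALSE)
  } else {
    ## greedy forward selection: grow the best subset one gene at a time
    subsets <- list()
    current <- character(0)
    for (k in seq_len(max_size)) {
      candidates <- setdiff(signature@genes, current)
      aucs <- vapply(candidates, function(g)
        evalSubset(c(current, g)), numeric(1))
      best <- candidates[order(-aucs, candidates)][1]
      current <- c(current, best)
      subsets[[k]] <- current
    }
  }
  auc <- vapply(subsets, evalSubset, numeric(1))
  sizes <- lengths(subsets)
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  ord <- order(-auc, sizes, keys)
  out <- data.frame(subset = keys[ord], size = sizes[ord],
                    cv_auc = auc[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
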