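## Survival and association statistics linking matreotypes and scores to
## outcome: Kaplan-Meier / log-rank, Cox proportional hazards (Efron ties),
## Fisher exact enrichment of categorical labels, and Mann-Whitney group
## comparisons with BH correction.

.checkSurvTable <- function(surv) {
  need <- c("time_months", "event")
  if (!all(need %in% colnames(surv)))
    stop("survival table requires columns ", paste(need, collapse = ", "))
  surv <- surv[complete.cases(surv[, need]), , drop = FALSE]
  if (any(surv$time_months <= 0)) stop("survival times must be positive")
  if (!all(surv$event %in% c(0, 1))) stop("event must be 0/1")
  surv
}

#' Ordinal encoding of tumor stage
#'
#' Maps roman-numeral stage labels (I, II, III, IV, optionally with
#' sub-stage letters, e.g. "IIA") to ordinal 1..4 for use as a Cox
#' covariate. Unrecognised values become NA.
#'
#' @param stage character vector of stage labels.
#' @return integer vector.
#' @export
stageToOrdinal <- function(stage) {
  core <- toupper(gsub("[ABab]$", "", trimws(as.character(stage))))
  unname(c(I = 1L, II = 2L, III = 3L, IV = 4L)[core])
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' Product-limit survival estimates per group and the k-group log-rank
#' test. When a group has no events it is retained in the KM estimates but
#' the test degrees of freedom are reduced to (groups with events) - 1,
#' with a warning.
#'
#' @param surv survival table with columns \code{time_months}, \code{event}
#'   (0/1) and optionally \code{sample_id}.
#' @param groups per-sample group labels aligned with the rows of
#'   \code{surv}.
#' @return list with \code{km} (data.frame: group, time, n_risk, n_event,
#'   survival), \code{chisq}, \code{df}, \code{p}.
#' @export
kmLogrank <- function(surv, groups) {
  groups <- as.character(groups)
  if (length(groups) != nrow(surv)) stop("groups must align with surv rows")
  keep <- complete.cases(surv[, c("time_months", "event")]) & !is.na(groups)
  surv <- .checkSurvTable(surv[keep, , drop = FALSE])
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  eventsPerGroup <- tapply(surv$event, groups, sum)
  if (any(eventsPerGroup == 0))
    warning("group(s) with zero events: ",
            paste(names(eventsPerGroup)[eventsPerGroup == 0], collapse = ", "),
            "; log-rank df reduced")
  s <- survival::Surv(surv$time_months, surv$event)
  fit <- survival::survfit(s ~ groups)
  strata <- rep(names(fit$strata), fit$strata)
  km <- data.frame(group = sub("^groups=", "", strata), time = fit$time,
                   n_risk = fit$n.risk, n_event = fit$n.event,
                   survival = fit$surv)
  sd <- survival::survdiff(s ~ groups)
  df <- max(1L, sum(eventsPerGroup > 0) - 1L)
  list(km = km, chisq = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional hazards model with covariate adjustment
#'
#' Fits a Cox model of survival on a group label (reference level =
#' first sorted label unless \code{reference} is given) or a numeric score,
#' optionally adjusted for clinical covariates (e.g. age and ordinal
#' stage), with Efron handling of ties. Reports hazard ratios with 95%
#' Wald confidence intervals per term.
#'
#' @param surv survival table (\code{time_months}, \code{event}) whose rows
#'   align with \code{groups_or_scores}; covariate columns are looked up
#'   here.
#' @param groups_or_scores group labels (character/factor) or a numeric
#'   per-sample score.
#' @param covariates character vector of covariate column names in
#'   \code{surv}; a \code{stage} column is ordinal-encoded via
#'   [stageToOrdinal()].
#' @param reference reference group label for categorical terms.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return data.frame with one row per model term: term, coef, HR, ci_lo,
#'   ci_hi, p, n, n_events.
#' @export
coxPH <- function(surv, groups_or_scores, covariates = character(0),
                  reference = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(groups_or_scores) != nrow(surv))
    stop("groups_or_scores must align with surv rows")
  df <- data.frame(time = surv$time_months, event = surv$event)
  if (is.numeric(groups_or_scores)) {
    df$term <- groups_or_scores
  } else {
    g <- factor(as.character(groups_or_scores))
    if (!is.null(reference)) g <- stats::relevel(g, ref = reference)
    df$term <- g
  }
  for (cv in covariates) {
    if (!cv %in% colnames(surv))
      stop("covariate '", cv, "' not found in the survival table")
    df[[cv]] <- if (cv == "stage") stageToOrdinal(surv[[cv]])
      else as.numeric(surv[[cv]])
  }
  df <- df[complete.cases(df), , drop = FALSE]
  df <- df[df$time > 0, , drop = FALSE]
  nTerms <- (if (is.factor(df$term)) nlevels(df$term) - 1L else 1L) +
    length(covariates)
  if (sum(df$event) < 5 * nTerms)
    warning("fewer than 5 events per model term (",
            sum(df$event), " events, ", nTerms, " terms)")
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ term",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + "))
    else ""))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        stop("numerical error: monotone likelihood / non-convergence; ",
             "consider stratifying or merging groups", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  out <- data.frame(term = rownames(cf), coef = cf[, "coef"],
                    HR = cf[, "exp(coef)"],
                    ci_lo = ci[, "lower .95"], ci_hi = ci[, "upper .95"],
                    p = cf[, "Pr(>|z|)"],
                    n = fit$n, n_events = fit$nevent)
  rownames(out) <- NULL
  out$term <- sub("^term", "", out$term)
  out
}

#' Fisher exact enrichment of categories between two labelings
#'
#' For every category of \code{labels_b}, builds the 2x2 table (category
#' vs rest) x (the two levels of \code{labels_a}) and computes the
#' two-sided Fisher exact p-value (sum of hypergeometric probabilities of
#' tables with probability at most that of the observed table). BH
#' adjustment is applied across categories.
#'
#' @param labels_a two-level labels (e.g. matreotype ECM-Low/ECM-High).
#' @param labels_b categorical labels on the same samples (e.g. canonical
#'   subtype).
#' @return data.frame per category: category, the four cell counts
#'   (\code{in_a1}, \code{in_a2}, \code{out_a1}, \code{out_a2}),
#'   odds_ratio, p_value, adj_p_value.
#' @export
fisherEnrichment <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must be aligned on the same samples")
  a <- factor(as.character(labels_a))
  if (nlevels(a) != 2L)
    stop("labels_a must have exactly 2 levels (pairwise mode required)")
  b <- factor(as.character(labels_b))
  res <- lapply(levels(b), function(cat) {
    tab <- rbind(table(a[b == cat]), table(a[b != cat]))
    ft <- fisher.test(tab, alternative = "two.sided")
    data.frame(category = cat,
               in_a1 = tab[1, 1], in_a2 = tab[1, 2],
               out_a1 = tab[2, 1], out_a2 = tab[2, 2],
               odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  })
  out <- do.call(rbind, res)
  out$adj_p_value <- p.adjust(out$p_value, method = "BH")
  out
}

#' Mann-Whitney group comparison with BH correction
#'
#' Two-sided rank-sum test per variable between two groups: exact
#' enumeration when both groups have at most 8 samples and no ties,
#' tie-corrected normal approximation otherwise. Variables constant across
#' both groups get p = 1 and are flagged.
#'
#' @param values numeric matrix, variables x samples.
#' @param groups two-level labels aligned with the columns.
#' @return data.frame per variable: variable, U (rank-sum statistic of the
#'   first group), p_value, adj_p_value, constant.
#' @export
groupCompareBH <- function(values, groups) {
  values <- as.matrix(values)
  groups <- .binaryClasses(groups, ncol(values))
  g1 <- groups == levels(groups)[1]
  if (sum(g1) < 2L || sum(!g1) < 2L)
    stop("both groups need >= 2 samples")
  res <- lapply(rownames(values), function(v) {
    x <- values[v, g1]
    y <- values[v, !g1]
    if (length(unique(c(x, y))) == 1L)
      return(data.frame(variable = v, U = length(x) * length(y) / 2,
                        p_value = 1, constant = TRUE))
    ties <- any(duplicated(c(x, y)))
    exact <- length(x) <= 8L && length(y) <= 8L && !ties
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = exact,
                  correct = FALSE))
    data.frame(variable = v, U = unname(wt$statistic),
               p_value = min(1, wt$p.value), constant = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p_value <- p.adjust(out$p_value, method = "BH")
  out[, c("variable", "U", "p_value", "adj_p_value", "constant")]
}
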