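## Ligand-receptor interaction scoring on z-scaled expression: per-pair
## products, max-aggregation to receptor classes or pathways, and
## moderated differential contrasts between matreotypes.

#' Ligand-receptor interaction scores
#'
#' For each (ligand, receptor) pair and sample, the interaction score is
#' the product of the z-scaled receptor and ligand expression,
#' \code{score = z(receptor) * z(ligand)}. Note the sign semantics:
#' co-depletion (both z negative) scores positive; \code{truncate_negative
#' = TRUE} zero-truncates z-values first so only co-expression scores.
#' Pairs with either gene absent are dropped and reported.
#'
#' @param z [ZScaledMatrix-class] or genes x samples matrix.
#' @param pairs ligand-receptor table ([readLigandReceptorPairs()]).
#' @param truncate_negative zero-truncate z before multiplying.
#' @return An [InteractionScoreMatrix-class].
#' @export
interactionScores <- function(z, pairs, truncate_negative = FALSE) {
  m <- .zmat(z)
  if (truncate_negative) m <- pmax(m, 0)
  ok <- pairs$ligand %in% rownames(m) & pairs$receptor %in% rownames(m)
  dropped <- pairs[!ok, , drop = FALSE]
  if (nrow(dropped))
    message("dropping ", nrow(dropped),
            " pair(s) with gene(s) absent from the matrix")
  pairs <- pairs[ok, , drop = FALSE]
  if (!nrow(pairs))
    stop("no usable ligand-receptor pair: all genes missing")
  scores <- m[pairs$receptor, , drop = FALSE] *
    m[pairs$ligand, , drop = FALSE]
  rownames(scores) <- paste(pairs$ligand, pairs$receptor, sep = "_")
  rownames(pairs) <- rownames(scores)
  new("InteractionScoreMatrix", scores = scores, pairs = pairs,
      dropped = dropped)
}

#' Aggregate interaction scores by receptor class or pathway
#'
#' Per group (receptor class, or each pathway a receptor maps to) and
#' sample, the aggregated value is the maximum interaction score over the
#' member pairs. The pair membership of each group is attached as an
#' attribute.
#'
#' @param scores an [InteractionScoreMatrix-class].
#' @param grouping \code{"receptor_class"} or \code{"pathway"} (pathways
#'   are split on ";" so a pair may belong to several).
#' @return numeric matrix, groups x samples, with
#'   \code{attr(, "membership")} listing member pairs per group.
#' @export
aggregateInteractions <- function(scores,
                                  grouping = c("receptor_class", "pathway")) {
  grouping <- match.arg(grouping)
  sc <- scores@scores
  pr <- scores@pairs
  membership <- if (grouping == "receptor_class") {
    split(rownames(sc), pr$receptor_class)
  } else {
    pw <- strsplit(ifelse(is.na(pr$pathways), "", pr$pathways), ";",
                   fixed = TRUE)
    pw <- lapply(pw, trimws)
    long <- data.frame(pair = rep(rownames(sc), lengths(pw)),
                       group = unlist(pw))
    long <- long[nzchar(long$group), , drop = FALSE]
    split(long$pair, long$group)
  }
  membership <- membership[lengths(membership) > 0]
  if (!length(membership)) stop("grouping covers no pair")
  agg <- t(vapply(membership, function(members)
    apply(sc[members, , drop = FALSE], 2L, max), numeric(ncol(sc))))
  dimnames(agg) <- list(names(membership), colnames(sc))
  attr(agg, "membership") <- membership
  agg
}

#' Differential ligand-receptor interactions between matreotypes
#'
#' Applies the same moderated linear-model machinery as the differential
#' expression stage to class- or pathway-aggregated interaction scores,
#' contrasting two matreotype groups. \code{logFC} is group 2 minus group 1
#' of the sorted labels (or the factor's level order).
#'
#' @param aggregated groups x samples matrix from
#'   [aggregateInteractions()] (or a pair-level score matrix).
#' @param groups two-level matreotype labels aligned with the columns;
#'   each level needs >= 2 samples.
#' @param alpha BH significance level.
#' @return data.frame with group, logFC, t, p_value, adj_p_value,
#'   significant.
#' @export
differentialInteractions <- function(aggregated, groups, alpha = 0.05) {
  tab <- .moderatedTwoGroup(as.matrix(aggregated), groups, alpha = alpha)
  colnames(tab)[colnames(tab) == "gene"] <- "group"
  tab
}
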