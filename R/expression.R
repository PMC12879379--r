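#' Aggregate expression per gene in target and background samples
#'
#' Sums normalized expression values across all samples of the target group
#' and of the background group, separately for each gene. The input matrix is
#' expected to be already normalized (e.g. DESeq size-factor normalized
#' counts); normalization is upstream of this toolkit.
#'
#' @param expr numeric matrix, genes x samples, with unique rownames
#'   (gene ids) and colnames (sample ids). No negative values.
#' @param sample_group named character vector mapping every sample id to
#'   `"target"` or `"background"`.
#' @return data.frame with columns `gene_id`, `agg_target`, `agg_background`.
#' @examples
#' expr <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' grp <- c(s1 = "target", s2 = "target", s3 = "background")
#' aggregate_expression(expr, grp)
#' @export
aggregate_expression <- function(expr, sample_group) {
  expr <- as.matrix(expr)
  stop_if_not(nrow(expr) > 0 && ncol(expr) > 0, "expression matrix is empty")
  stop_if_not(!anyNA(expr) && all(expr >= 0),
              "expression values must be non-negative and non-missing")
  stop_if_not(!is.null(rownames(expr)) && !anyDuplicated(rownames(expr)),
              "gene ids (rownames) must be present and unique")
  stop_if_not(!is.null(colnames(expr)), "sample ids (colnames) are required")
  stop_if_not(all(colnames(expr) %in% names(sample_group)),
              "every sample needs a group label")
  grp <- sample_group[colnames(expr)]
  stop_if_not(all(grp %in% c("target", "background")),
              "group labels must be 'target' or 'background'")
  for (g in c("target", "background")) {
    if (!any(grp == g)) {
      stop(sprintf("group '%s' has no samples", g), call. = FALSE)
    }
  }
  data.frame(
    gene_id = rownames(expr),
    agg_target = rowSums(expr[, grp == "target", drop = FALSE]),
    agg_background = rowSums(expr[, grp == "background", drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Drop genes with low aggregate expression in the target cells
#'
#' Removes genes whose target-group aggregate lies strictly below the median
#' target aggregate, computed over all genes before filtering. Genes exactly
#' at the median are kept.
#'
#' @param aggregates data.frame from [aggregate_expression()].
#' @return the retained rows, with the applied median in attribute
#'   `"median"`.
#' @export
median_filter <- function(aggregates) {
  stop_if_not(nrow(aggregates) >= 1, "no genes to filter")
  med <- median(aggregates$agg_target)
  out <- aggregates[aggregates$agg_target >= med, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "median") <- med
  out
}

#' Specificity scores from aggregate expression
#'
#' Ranks genes from high to low by target aggregate and from low to high by
#' background aggregate (average ranks on ties), sums the two ranks, and
#' ranks that sum ascending to give the specificity score: small scores mark
#' genes specifically expressed in the target cell type.
#'
#' @param aggregates data.frame with `gene_id`, `agg_target`,
#'   `agg_background` (typically after [median_filter()]).
#' @return data.frame adding `rank_target`, `rank_background`, `rank_sum`,
#'   `specificity_score`.
#' @export
specificity_scores <- function(aggregates) {
  stop_if_not(nrow(aggregates) >= 1, "empty aggregate table")
  out <- aggregates
  out$rank_target <- rank(-out$agg_target, ties.method = "average")
  out$rank_background <- rank(out$agg_background, ties.method = "average")
  out$rank_sum <- out$rank_target + out$rank_background
  out$specificity_score <- rank(out$rank_sum, ties.method = "average")
  rownames(out) <- NULL
  out
}

#' Partition genes into top-ranked, comparator and bottom-ranked sets
#'
#' Thresholds the score distribution at `mu - k_top * sigma` (strictly
#' below: top-ranked set) and `mu - k_comp * sigma` (strictly above:
#' comparator set), leaving a zone of exclusion in between; `mu` and
#' `sigma` are the mean and population SD of the scores. The bottom-ranked
#' control set holds as many genes as the top set, taken from the largest
#' scores.
#'
#' The thresholded score is the rank sum itself, not its re-rank: for
#' unspecific genes the descending target rank and ascending background
#' rank are strongly anticorrelated, so the rank-sum distribution is
#' tightly concentrated near n + 1 and genes specific to the target cells
#' fall many SDs below its mean. (A re-ranked score is uniform on 1..n and
#' can never lie more than sqrt(3) SDs from its mean, which would make the
#' thresholds vacuous.)
#'
#' @param scores data.frame from [specificity_scores()].
#' @param k_top SDs below the mean for the top-set threshold (default 4).
#' @param k_comp SDs below the mean for the comparator threshold (default 3).
#' @param score_col column holding the thresholded score (default
#'   `"rank_sum"`).
#' @return list with `top`, `comparator`, `bottom` (character gene ids),
#'   `mu`, `sigma`, `k_top`, `k_comp`.
#' @export
partition_gene_sets <- function(scores, k_top = 4, k_comp = 3,
                                score_col = "rank_sum") {
  stop_if_not(nrow(scores) >= 3, "need at least 3 genes to partition")
  stop_if_not(score_col %in% names(scores),
              sprintf("scores table lacks a '%s' column", score_col))
  s <- scores[[score_col]]
  mu <- mean(s)
  sigma <- pop_sd(s)
  top <- scores$gene_id[s < mu - k_top * sigma]
  comparator <- scores$gene_id[s > mu - k_comp * sigma]
  if (length(top) == 0) {
    warning("no gene lies ", k_top, " SDs below the mean specificity score; ",
            "top and bottom sets are empty")
    bottom <- character(0)
  } else {
    ord <- order(-s, scores$gene_id)
    bottom <- scores$gene_id[ord][seq_along(top)]
  }
  list(top = top, comparator = comparator, bottom = bottom,
       mu = mu, sigma = sigma, k_top = k_top, k_comp = k_comp)
}

#' Rank genes by target-cell specificity and partition them
#'
#' Convenience pipeline: [aggregate_expression()], [median_filter()],
#' [specificity_scores()], [partition_gene_sets()].
#'
#' @inheritParams aggregate_expression
#' @inheritParams partition_gene_sets
#' @return list with the partition (see [partition_gene_sets()]) plus the
#'   score table (`scores`) and the applied median filter value
#'   (`median_target`).
#' @export
rank_genes <- function(expr, sample_group, k_top = 4, k_comp = 3) {
  agg <- aggregate_expression(expr, sample_group)
  kept <- median_filter(agg)
  scores <- specificity_scores(kept)
  part <- partition_gene_sets(scores, k_top = k_top, k_comp = k_comp)
  c(part, list(scores = scores, median_target = attr(kept, "median")))
}
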