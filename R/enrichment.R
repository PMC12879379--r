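# Monte Carlo enrichment of motifs and motif pairs in gene-linked
# regulatory regions, and candidate selection for the reporter library.

#' Gene x motif presence table
#'
#' `presence[g, m]` is `TRUE` when at least one of gene g's linked regions
#' of the requested class contains at least one (already filtered) hit of
#' motif m. Class `"both"` is the union of proximal and distal presence.
#'
#' @param map a `gene_region_map` from [build_gene_region_map()].
#' @param hits hit table from [scan_motifs()], already filtered by p-value
#'   and any score cutoff.
#' @param motifs motif ids for the columns (default: all in `hits`).
#' @param region_class `"both"`, `"proximal"` or `"distal"`.
#' @param genes gene universe for the rows (default: all genes in the TSS
#'   table; genes without qualifying regions get all-`FALSE` rows).
#' @return logical matrix, genes x motifs.
#' @export
presence_table <- function(map, hits,
                           motifs = sort(unique(hits$motif_id)),
                           region_class = c("both", "proximal", "distal"),
                           genes = sort(unique(map$tss$gene_id))) {
  region_class <- match.arg(region_class)
  links <- map$links
  if (region_class != "both") {
    links <- links[links$region_class == region_class, , drop = FALSE]
  }
  out <- matrix(FALSE, nrow = length(genes), ncol = length(motifs),
                dimnames = list(genes, motifs))
  if (nrow(links) == 0 || nrow(hits) == 0) return(out)
  hits <- hits[hits$motif_id %in% motifs, , drop = FALSE]
  hit_regions <- split(hits$region_id, hits$motif_id)
  regions_by_gene <- split(links$region_id, links$gene_id)
  for (m in names(hit_regions)) {
    with_hit <- unique(hit_regions[[m]])
    pres <- vapply(genes, function(g) {
      any(regions_by_gene[[g]] %in% with_hit)
    }, logical(1))
    out[, m] <- pres
  }
  out
}

#' Presence of a motif pair
#'
#' A gene carries the pair when it carries both motifs, in any of its
#' regions of the class (not necessarily the same region).
#'
#' @param presence logical gene x motif matrix from [presence_table()].
#' @param pair character vector of two motif ids.
#' @return named logical vector over genes.
#' @export
pair_presence <- function(presence, pair) {
  stop_if_not(length(pair) == 2, "a pair needs exactly two motifs")
  stop_if_not(all(pair %in% colnames(presence)),
              "both motifs must be columns of the presence table")
  setNames(presence[, pair[1]] & presence[, pair[2]], rownames(presence))
}

#' Monte Carlo enrichment test for one motif (or pair)
#'
#' Counts the target genes carrying the motif, then draws `n_iter`
#' size-matched gene sets from the comparator set without replacement and
#' counts carriers in each. The p-value is the fraction of iterations whose
#' sampled count reaches the observed count; fold change is observed over
#' the null mean. A subject is called enriched when p < `p_max` and fold
#' change > `fold_min`.
#'
#' @param presence named logical vector over genes (a [presence_table()]
#'   column or [pair_presence()] result).
#' @param target_genes,comparator_genes character gene ids; the comparator
#'   set must be at least as large as the target set.
#' @param n_iter Monte Carlo iterations (default 10,000).
#' @param seed optional RNG seed, recorded in the result.
#' @param subject label for the result row.
#' @param p_max,fold_min enrichment call thresholds (defaults 0.05 and 2).
#' @return one-row data.frame: `subject`, `observed`, `null_mean`,
#'   `p_value`, `fold_change`, `enriched`, `n_iter`, `seed`.
#' @export
mc_test <- function(presence, target_genes, comparator_genes,
                    n_iter = 10000, seed = NULL, subject = NA_character_,
                    p_max = 0.05, fold_min = 2) {
  stop_if_not(n_iter >= 1, "n_iter must be at least 1")
  stop_if_not(length(comparator_genes) >= length(target_genes),
              "comparator set smaller than target set")
  stop_if_not(all(c(target_genes, comparator_genes) %in% names(presence)),
              "all genes must appear in the presence vector")
  observed <- sum(presence[target_genes])
  comp <- unname(presence[comparator_genes])
  k <- length(target_genes)
  n <- length(comparator_genes)
  counts <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) sum(comp[sample.int(n, k)]),
           numeric(1))
  })
  null_mean <- mean(counts)
  p_value <- sum(counts >= observed) / n_iter
  fold_change <- if (null_mean == 0) {
    if (observed > 0) Inf else NaN
  } else {
    observed / null_mean
  }
  enriched <- observed > 0 && p_value < p_max &&
    (is.infinite(fold_change) || fold_change > fold_min)
  data.frame(subject = subject, observed = observed, null_mean = null_mean,
             p_value = p_value, fold_change = fold_change,
             enriched = enriched, n_iter = n_iter,
             seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}

#' Enumerate motif pairs
#'
#' @param ids motif identifiers.
#' @param mode `"unordered"` for distinct unordered pairs, `"cross"` for
#'   the full ordered cross-product including self-pairs (the convention
#'   behind an n^2 pair universe).
#' @return data.frame with `motif1`, `motif2`.
#' @export
enumerate_pairs <- function(ids, mode = c("unordered", "cross")) {
  mode <- match.arg(mode)
  if (mode == "cross") {
    out <- expand.grid(motif2 = ids, motif1 = ids,
                       stringsAsFactors = FALSE)[, c("motif1", "motif2")]
  } else {
    stop_if_not(length(ids) >= 2, "need at least two motifs for pairs")
    cmb <- combn(ids, 2)
    out <- data.frame(motif1 = cmb[1, ], motif2 = cmb[2, ],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Run the Monte Carlo test over all motifs or pairs of a presence table
#'
#' @param presence logical gene x motif matrix.
#' @inheritParams mc_test
#' @param pairs if `TRUE`, test motif pairs instead of single motifs.
#' @param pair_mode pair universe, see [enumerate_pairs()].
#' @return data.frame of [mc_test()] rows; pair subjects are
#'   `"motif1;motif2"`.
#' @export
enrich_test <- function(presence, target_genes, comparator_genes,
                        n_iter = 10000, seed = NULL, pairs = FALSE,
                        pair_mode = c("unordered", "cross"),
                        p_max = 0.05, fold_min = 2) {
  subjects <- if (pairs) {
    pr <- enumerate_pairs(colnames(presence), mode = match.arg(pair_mode))
    lapply(seq_len(nrow(pr)), function(i) c(pr$motif1[i], pr$motif2[i]))
  } else {
    as.list(colnames(presence))
  }
  seeds <- if (is.null(seed)) vector("list", length(subjects)) else
    as.list(seed + seq_along(subjects) - 1L)
  res <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    vec <- if (length(s) == 2) pair_presence(presence, s) else
      setNames(presence[, s], rownames(presence))
    mc_test(vec, target_genes, comparator_genes, n_iter = n_iter,
            seed = seeds[[i]], subject = paste(s, collapse = ";"),
            p_max = p_max, fold_min = fold_min)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter TFBS motifs by transcription-factor expression
#'
#' A known motif is retained only when every transcription-factor gene it
#' maps to (dimer motifs map to several) reaches the aggregate-expression
#' threshold in the target cells. Motifs without a mapping are retained
#' with a warning.
#'
#' @param motif_ids character vector of known-motif ids.
#' @param motif_genes named list: motif id -> character vector of TF gene
#'   ids.
#' @param agg_target named numeric: gene -> target-cell aggregate
#'   expression.
#' @param threshold minimum aggregate expression.
#' @return character vector of retained motif ids.
#' @export
expression_filter_tfbs <- function(motif_ids, motif_genes, agg_target,
                                   threshold) {
  unmapped <- setdiff(motif_ids, names(motif_genes))
  if (length(unmapped) > 0) {
    warning(length(unmapped),
            " motif(s) without a TF gene mapping were retained")
  }
  keep <- vapply(motif_ids, function(m) {
    genes <- motif_genes[[m]]
    if (is.null(genes)) return(TRUE)
    vals <- agg_target[genes]
    all(!is.na(vals) & vals >= threshold)
  }, logical(1))
  motif_ids[keep]
}

#' Rank motif pairs for candidate selection
#'
#' Pairs are ranked by (1) the observed number of target genes, descending,
#' and (2) the mean sampled comparator count, ascending; the two ranks are
#' summed and the final order is ascending in that sum, ties broken
#' lexicographically by subject.
#'
#' @param results data.frame of [mc_test()] rows (one region class).
#' @return `results` reordered, with `rank_observed`, `rank_null` and
#'   `rank_sum` columns added.
#' @export
rank_pairs <- function(results) {
  results$rank_observed <- rank(-results$observed, ties.method = "average")
  results$rank_null <- rank(results$null_mean, ties.method = "average")
  results$rank_sum <- results$rank_observed + results$rank_null
  out <- results[order(results$rank_sum, results$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate motifs for the reporter library
#'
#' Walks the ranked TFBS:TFBS pair list collecting member TFBS (skipping
#' any whose DNA-binding archetype is already represented) until `n_tfbs`
#' are found, then walks the ranked TFBS:novel list restricted to pairs
#' containing a selected TFBS, collecting novel motifs until `n_novel`.
#'
#' @param ranked_tt data.frame with `motif1`, `motif2` (both TFBS) in final
#'   rank order (see [rank_pairs()]).
#' @param ranked_tn data.frame with `motif1` (TFBS), `motif2` (novel) in
#'   final rank order.
#' @param archetype_map named character: TFBS motif id -> archetype.
#' @param n_tfbs,n_novel selection quotas (defaults 9 and 9).
#' @return list with `tfbs` and `novel` character vectors; a warning is
#'   emitted if a list is exhausted before its quota.
#' @export
select_candidates <- function(ranked_tt, ranked_tn, archetype_map,
                              n_tfbs = 9, n_novel = 9) {
  tfbs <- character(0)
  used_arch <- character(0)
  for (i in seq_len(nrow(ranked_tt))) {
    for (m in c(ranked_tt$motif1[i], ranked_tt$motif2[i])) {
      if (length(tfbs) >= n_tfbs) break
      if (m %in% tfbs) next
      arch <- if (m %in% names(archetype_map)) archetype_map[[m]] else
        NA_character_
      if (!is.na(arch) && arch %in% used_arch) next
      tfbs <- c(tfbs, m)
      if (!is.na(arch)) used_arch <- c(used_arch, arch)
    }
    if (length(tfbs) >= n_tfbs) break
  }
  if (length(tfbs) < n_tfbs) {
    warning("TFBS pair list exhausted: selected ", length(tfbs), " of ",
            n_tfbs)
  }
  novel <- character(0)
  for (i in seq_len(nrow(ranked_tn))) {
    if (length(novel) >= n_novel) break
    if (!(ranked_tn$motif1[i] %in% tfbs)) next
    m <- ranked_tn$motif2[i]
    if (m %in% novel) next
    novel <- c(novel, m)
  }
  if (length(novel) < n_novel) {
    warning("TFBS:novel pair list exhausted: selected ", length(novel),
            " of ", n_novel)
  }
  list(tfbs = tfbs, novel = novel)
}

#' Representative natural site for a motif
#'
#' Among the genomic subsequences matched by the motif's hits, returns the
#' most frequent; ties go to the highest scan score, remaining ties to the
#' lexicographically smallest sequence.
#'
#' @param motif_id motif identifier.
#' @param hits hit table from [scan_motifs()] (its `match` column holds the
#'   matched sequences in motif orientation).
#' @return character scalar site sequence.
#' @export
representative_site <- function(motif_id, hits) {
  h <- hits[hits$motif_id == motif_id, , drop = FALSE]
  stop_if_not(nrow(h) >= 1, sprintf("no hits for motif %s", motif_id))
  freq <- table(h$match)
  best_score <- vapply(names(freq), function(s) {
    max(h$score[h$match == s])
  }, numeric(1))
  ord <- order(-as.integer(freq), -best_score, names(freq))
  names(freq)[ord[1]]
}
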