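# Motif-motif similarity: mean per-column Pearson correlation over the best
# gapless alignment (offset and strand), and the filters built on it.

.align_score <- function(a, b, min_overlap) {
  # max over offsets d of mean per-column Pearson between a[, j] and
  # b[, j - d] for aligned j; returns c(score, offset). Column correlations
  # are computed for a whole offset at once.
  la <- ncol(a); lb <- ncol(b)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  assd <- colSums(ac^2); bssd <- colSums(bc^2)
  best <- c(score = -Inf, offset = 0)
  for (d in seq(-(lb - min_overlap), la - min_overlap)) {
    js <- seq(max(1, 1 + d), min(la, lb + d))
    if (length(js) < min_overlap) next
    ks <- js - d
    num <- colSums(ac[, js, drop = FALSE] * bc[, ks, drop = FALSE])
    den <- sqrt(assd[js] * bssd[ks])
    is_flat <- assd[js] < 1e-20 | bssd[ks] < 1e-20
    r <- numeric(length(js))
    r[!is_flat] <- num[!is_flat] / den[!is_flat]
    # constant-column convention: r = 1 iff the columns are identical
    for (f in which(is_flat)) {
      r[f] <- as.numeric(max(abs(a[, js[f]] - b[, ks[f]])) < 1e-9)
    }
    s <- mean(r)
    if (s > best["score"]) best <- c(score = s, offset = d)
  }
  best
}

#' Similarity between two motifs
#'
#' Aligns the probability columns of two PPMs at every gapless offset with
#' at least `min_overlap` aligned columns, on the forward strand and against
#' the reverse complement of `b`, and returns the best mean per-column
#' Pearson correlation. Columns with zero variance follow a constant-column
#' convention (r = 1 if the columns are equal, 0 otherwise). This is a
#' deliberately simple alignment statistic in the spirit of motif-comparison
#' tools, without their null-model p-values.
#'
#' @param a,b [ppm] objects.
#' @param min_overlap minimum number of aligned columns (default 8).
#' @return list with `score`, `offset` (columns of `a` skipped before `b`
#'   starts; negative if `b` overhangs left) and `strand` (`"+"`/`"-"`).
#' @examples
#' p <- build_ppm(c("ACGTACGTACGT"))
#' motif_similarity(p, p)$score
#' @export
motif_similarity <- function(a, b, min_overlap = 8) {
  stop_if_not(min_overlap >= 1, "min_overlap must be >= 1")
  stop_if_not(min_overlap <= min(ncol(a$matrix), ncol(b$matrix)),
              "min_overlap exceeds a motif length")
  fwd <- .align_score(a$matrix, b$matrix, min_overlap)
  rev <- .align_score(a$matrix, rc_ppm(b)$matrix, min_overlap)
  if (rev["score"] > fwd["score"]) {
    list(score = unname(rev["score"]), offset = unname(rev["offset"]),
         strand = "-")
  } else {
    list(score = unname(fwd["score"]), offset = unname(fwd["offset"]),
         strand = "+")
  }
}

#' Remove novel motifs that match known motifs
#'
#' A novel PPM is dropped when its best [motif_similarity()] score against
#' any known PPM reaches `r_match`.
#'
#' @param novel list of novel [ppm]s.
#' @param known list of known [ppm]s; if `NULL` or empty all novel motifs
#'   are retained.
#' @param r_match similarity threshold (default 0.75).
#' @param min_overlap minimum aligned columns.
#' @return list with `retained` (novel PPMs kept) and `matched`
#'   (data.frame `novel_id`, `known_id`, `score` of removals).
#' @export
filter_known <- function(novel, known, r_match = 0.75, min_overlap = 8) {
  matched <- data.frame(novel_id = character(0), known_id = character(0),
                        score = numeric(0), stringsAsFactors = FALSE)
  if (is.null(known) || length(known) == 0) {
    return(list(retained = novel, matched = matched))
  }
  drop <- logical(length(novel))
  for (i in seq_along(novel)) {
    best <- -Inf; best_id <- NA_character_
    for (kn in known) {
      s <- motif_similarity(novel[[i]], kn, min_overlap = min_overlap)$score
      if (s > best) { best <- s; best_id <- kn$motif_id }
      if (best >= r_match) break
    }
    if (best >= r_match) {
      drop[i] <- TRUE
      matched <- rbind(matched, data.frame(
        novel_id = novel[[i]]$motif_id, known_id = best_id, score = best,
        stringsAsFactors = FALSE))
    }
  }
  list(retained = novel[!drop], matched = matched)
}

#' Collapse redundant motifs to representatives
#'
#' Greedy single-linkage clustering: motifs whose pairwise similarity
#' reaches `r_cluster` fall into one cluster (chained through shared
#' members). Each cluster is represented by its member with the largest
#' `total_weight`, ties broken by lexicographic motif id; representatives
#' are returned in order of their cluster's first appearance.
#'
#' @param ppms list of [ppm] objects.
#' @param r_cluster similarity threshold (default 0.9).
#' @param min_overlap minimum aligned columns for similarity.
#' @return list of representative [ppm]s.
#' @export
cluster_redundant <- function(ppms, r_cluster = 0.9, min_overlap = 8) {
  n <- length(ppms)
  if (n <= 1) return(ppms)
  cluster <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    hits <- integer(0)
    for (j in seq_len(i - 1L)) {
      s <- motif_similarity(ppms[[i]], ppms[[j]],
                            min_overlap = min_overlap)$score
      if (s >= r_cluster) hits <- c(hits, cluster[j])
    }
    hits <- unique(hits)
    if (length(hits) == 0) {
      next_id <- next_id + 1L
      cluster[i] <- next_id
    } else {
      keep <- min(hits)
      cluster[i] <- keep
      cluster[cluster %in% hits] <- keep   # single linkage: merge chains
    }
  }
  reps <- lapply(sort(unique(cluster)), function(cid) {
    members <- ppms[cluster == cid]
    w <- vapply(members, function(p) {
      if (is.na(p$total_weight)) 0 else p$total_weight
    }, numeric(1))
    ids <- vapply(members, `[[`, "", "motif_id")
    members[[order(-w, ids)[1]]]
  })
  names(reps) <- vapply(reps, `[[`, "", "motif_id")
  reps
}
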