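# PWM construction, exact score-distribution p-values via dynamic
# programming over discretized column scores, and two-strand scanning.

#' Convert a PPM to a log-odds position weight matrix
#'
#' Entry (b, j) is `log2(((p[b,j] + pc) / (1 + 4 pc)) / background[b])`: a
#' small pseudocount regularises zero probabilities before the log.
#'
#' @param x a [ppm] object.
#' @param background length-4 background letter probabilities (A, C, G, T),
#'   summing to 1. Default uniform.
#' @param pseudocount probability added to every entry before the log
#'   (default 1e-4).
#' @return object of class `pwm`: list with `motif_id`, `matrix` (4 x L
#'   log2-odds), `background`, `pseudocount`.
#' @export
ppm_to_pwm <- function(x, background = rep(0.25, 4), pseudocount = 1e-4) {
  stop_if_not(length(background) == 4 && abs(sum(background) - 1) <= 1e-9,
              "background must be 4 probabilities summing to 1")
  stop_if_not(all(background > 0), "background probabilities must be positive")
  m <- log2(((x$matrix + pseudocount) / (1 + 4 * pseudocount)) / background)
  rownames(m) <- DNA_BASES
  structure(list(motif_id = x$motif_id, matrix = m,
                 background = setNames(as.numeric(background), DNA_BASES),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s: %d columns, max score %.3f\n",
              x$motif_id, ncol(x$matrix), sum(apply(x$matrix, 2, max))))
  invisible(x)
}

# Exact distribution of the PWM score of an iid-background L-mer, on a
# discretized score grid. Returns list(granularity, min_int, tail) where
# tail[i] = P(score >= (min_int + i - 1) * granularity).
score_distribution <- function(pwm, granularity = 1e-3) {
  d <- round(pwm$matrix / granularity)   # 4 x L integer column scores
  bg <- pwm$background
  # letters with -Inf scores (zero probability, zero pseudocount) sink all
  # their mass below every finite score; drop them from the convolution so
  # tail probabilities over finite scores stay exact
  finite_cols <- lapply(seq_len(ncol(d)), function(j) which(is.finite(d[, j])))
  stop_if_not(all(lengths(finite_cols) > 0),
              "a PWM column has no finite score")
  j1 <- finite_cols[[1]]
  cur_lo <- min(d[j1, 1])
  cur_hi <- max(d[j1, 1])
  probs <- numeric(cur_hi - cur_lo + 1)
  for (b in j1) {
    i <- d[b, 1] - cur_lo + 1
    probs[i] <- probs[i] + bg[b]
  }
  for (j in seq_len(ncol(d))[-1]) {
    jf <- finite_cols[[j]]
    new_lo <- cur_lo + min(d[jf, j])
    new_hi <- cur_hi + max(d[jf, j])
    new <- numeric(new_hi - new_lo + 1)
    for (b in jf) {
      off <- (cur_lo + d[b, j]) - new_lo
      rng <- seq_along(probs) + off
      new[rng] <- new[rng] + bg[b] * probs
    }
    cur_lo <- new_lo
    cur_hi <- new_hi
    probs <- new
  }
  tail <- rev(cumsum(rev(probs)))
  tail <- pmin(tail, 1)
  list(granularity = granularity, min_int = cur_lo, tail = tail)
}

.tail_lookup <- function(dist, scores) {
  .tail_at(dist, round(scores / dist$granularity), scores == -Inf)
}

# tail probability at integer grid positions (already-discretized sums)
.tail_at <- function(dist, ints, neg_inf = rep(FALSE, length(ints))) {
  idx <- ints - dist$min_int + 1
  idx <- pmin(pmax(idx, 1), length(dist$tail) + 1)
  out <- c(dist$tail, 0)[idx]
  out[which(neg_inf)] <- 1
  out
}

#' Exact p-value of a PWM score
#'
#' Probability that a random iid-background sequence of the motif's length
#' scores at least `score`, computed by dynamic programming over column
#' scores discretized to `granularity` (the only source of error).
#'
#' @param pwm a `pwm` object from [ppm_to_pwm()].
#' @param score numeric vector of log2-odds scores.
#' @param granularity discretization step (default 1e-3).
#' @return numeric vector of p-values in (0, 1].
#' @export
score_pvalue <- function(pwm, score, granularity = 1e-3) {
  dist <- score_distribution(pwm, granularity = granularity)
  p <- .tail_lookup(dist, score)
  # with an all-finite matrix every sequence scores at least the columnwise
  # minimum; rounding the queried total must not push the tail below 1 there
  if (all(is.finite(pwm$matrix))) {
    p[which(score <= sum(apply(pwm$matrix, 2, min)))] <- 1
  }
  pmax(p, .Machine$double.xmin)
}

.encode_dna <- function(sequence) {
  m <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], DNA_BASES)
  m  # NA for N and other ambiguity codes
}

.window_scores <- function(mat, codes) {
  L <- ncol(mat)
  n <- length(codes) - L + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    s <- s + mat[, j][codes[j:(j + n - 1)]]  # NA codes poison the window
  }
  s
}

#' Scan sequences for motif occurrences on both strands
#'
#' Scores every window of each sequence with the PWM on the forward strand
#' and with its reverse complement (reported as strand `"-"`), and reports
#' windows whose exact p-value is at most `p_thresh` and, when given, whose
#' score exceeds `score_min`. Windows containing `N` are skipped; all
#' overlapping hits are reported.
#'
#' @param pwm a `pwm` object.
#' @param sequences named character vector (or `DNAStringSet`); names become
#'   `region_id`s.
#' @param p_thresh p-value threshold (default 1e-4).
#' @param score_min optional score lower bound, exclusive (the pipeline
#'   derives it with [derive_score_cutoff()]).
#' @param granularity p-value discretization step.
#' @param dist optional precomputed [score_distribution()] (internal reuse).
#' @return data.frame with `motif_id`, `region_id`, `offset` (0-based),
#'   `strand`, `score`, `p_value`, `match` (the matched sequence, reverse
#'   complemented for `-` hits so it reads in motif orientation).
#' @export
scan_sequences <- function(pwm, sequences, p_thresh = 1e-4, score_min = NULL,
                           granularity = 1e-3, dist = NULL) {
  nm <- names(sequences)
  sequences <- as.character(sequences)
  names(sequences) <- if (is.null(nm))
    sprintf("seq%d", seq_along(sequences)) else nm
  if (is.null(dist)) dist <- score_distribution(pwm, granularity = granularity)
  L <- ncol(pwm$matrix)
  # p-values live on the discretized grid: sum per-column rounded scores so
  # window p-values match the DP distribution exactly
  dmat <- round(pwm$matrix / dist$granularity)
  rc_mat <- pwm$matrix[4:1, rev(seq_len(L)), drop = FALSE]
  rc_dmat <- dmat[4:1, rev(seq_len(L)), drop = FALSE]
  rownames(rc_mat) <- rownames(rc_dmat) <- DNA_BASES
  res <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    codes <- .encode_dna(sequences[[i]])
    fwd <- .window_scores(pwm$matrix, codes)
    rev <- .window_scores(rc_mat, codes)
    if (length(fwd) == 0) next
    hits <- list()
    for (str in c("+", "-")) {
      sc <- if (str == "+") fwd else rev
      disc <- .window_scores(if (str == "+") dmat else rc_dmat, codes)
      p <- .tail_at(dist, disc, sc == -Inf)
      keep <- which(!is.na(sc) & p <= p_thresh)
      if (!is.null(score_min)) keep <- keep[sc[keep] > score_min]
      if (length(keep) == 0) next
      match_seq <- substring(sequences[[i]], keep, keep + L - 1)
      if (str == "-") match_seq <- revcomp(match_seq)
      hits[[str]] <- data.frame(
        motif_id = pwm$motif_id, region_id = names(sequences)[i],
        offset = keep - 1L, strand = str, score = sc[keep],
        p_value = pmax(p[keep], .Machine$double.xmin), match = match_seq,
        stringsAsFactors = FALSE)
    }
    res[[i]] <- do.call(rbind, hits)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(motif_id = character(0), region_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0),
                      match = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Scan many motifs over many sequences
#'
#' @param pwms list of `pwm` objects (or [ppm]s, converted with defaults).
#' @inheritParams scan_sequences
#' @return combined hit data.frame (see [scan_sequences()]).
#' @export
scan_motifs <- function(pwms, sequences, p_thresh = 1e-4, score_min = NULL,
                        granularity = 1e-3) {
  pwms <- lapply(pwms, function(p) if (is(p, "ppm")) ppm_to_pwm(p) else p)
  out <- lapply(pwms, scan_sequences, sequences = sequences,
                p_thresh = p_thresh, score_min = score_min,
                granularity = granularity)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Derive a score cutoff from observed hits
#'
#' The arithmetic mean hit score; the pipeline uses the mean score of all
#' predicted occurrences in the regulatory regions of the top-ranked genes
#' as a data-derived score floor for enrichment analyses.
#'
#' @param hits hit data.frame from [scan_sequences()].
#' @return numeric scalar.
#' @export
derive_score_cutoff <- function(hits) {
  stop_if_not(nrow(hits) >= 1, "no hits to derive a cutoff from")
  mean(hits$score)
}
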