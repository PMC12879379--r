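# STARR-seq count QC, CPM normalization, background-adjusted activity
# scoring, and the motif-grammar statistics (orientation, copy number,
# position, pair, synergy, order).

#' Quality-filter oligos on DNA and RNA counts
#'
#' Retains oligos whose DNA count reaches `min_dna` in every DNA replicate
#' and whose RNA count is positive in at least `min_rna_reps` RNA
#' replicates.
#'
#' @param dna,rna integer count matrices (oligos x replicates) sharing
#'   rownames.
#' @param min_dna minimum DNA count per replicate (default 10).
#' @param min_rna_reps minimum RNA replicates with a positive count
#'   (default 2).
#' @return character vector of retained oligo ids; empty result is an
#'   error.
#' @export
qc_filter <- function(dna, rna, min_dna = 10, min_rna_reps = 2) {
  shared <- intersect(rownames(dna), rownames(rna))
  stop_if_not(length(shared) > 0, "DNA and RNA matrices share no oligos")
  ok_dna <- rowSums(dna[shared, , drop = FALSE] >= min_dna) == ncol(dna)
  ok_rna <- rowSums(rna[shared, , drop = FALSE] > 0) >= min_rna_reps
  kept <- shared[ok_dna & ok_rna]
  if (length(kept) == 0) stop("no oligo passes QC", call. = FALSE)
  kept
}

#' Counts-per-million normalization
#'
#' @param counts count matrix (oligos x replicates).
#' @return matrix with every replicate column scaled to sum to 1e6.
#' @export
cpm <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0)) stop("replicate with zero total count", call. = FALSE)
  sweep(counts, 2, totals, "/") * 1e6
}

#' Background-adjusted activity scores
#'
#' DNA replicates are collapsed to a per-oligo mean CPM; each RNA replicate
#' then yields `log2(RNA CPM / mean DNA CPM)` wherever both are positive,
#' and the activity of the motif-free background oligo is subtracted per
#' replicate, pinning the background's adjusted activity to zero.
#'
#' @param dna_cpm,rna_cpm CPM matrices (see [cpm()]) sharing rownames.
#' @param background_oligo_id id of the motif-free background oligo (must
#'   pass QC).
#' @return object of class `activity_matrix`: list with `scores` (adjusted
#'   oligo x RNA-replicate matrix), `raw` (unadjusted), `oligo_mean` (mean
#'   adjusted score over available replicates), `background_oligo_id`,
#'   `background_adjusted = TRUE`.
#' @export
activity <- function(dna_cpm, rna_cpm, background_oligo_id) {
  shared <- intersect(rownames(dna_cpm), rownames(rna_cpm))
  stop_if_not(background_oligo_id %in% shared,
              "background oligo absent from the count matrices")
  dna_mean <- rowMeans(dna_cpm[shared, , drop = FALSE])
  rna <- rna_cpm[shared, , drop = FALSE]
  raw <- log2(sweep(rna, 1, dna_mean, "/"))
  raw[rna <= 0 | dna_mean <= 0] <- NA
  bg <- raw[background_oligo_id, ]
  if (anyNA(bg)) {
    drop <- which(is.na(bg))
    warning("background oligo missing in RNA replicate(s) ",
            paste(colnames(raw)[drop], collapse = ", "), "; dropped")
    raw <- raw[, -drop, drop = FALSE]
    bg <- bg[-drop]
  }
  adjusted <- sweep(raw, 2, bg, "-")
  oligo_mean <- rowMeans(adjusted, na.rm = TRUE)
  oligo_mean[is.nan(oligo_mean)] <- NA
  structure(list(scores = adjusted, raw = raw, oligo_mean = oligo_mean,
                 background_oligo_id = background_oligo_id,
                 background_adjusted = TRUE),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("activity_matrix: %d oligos x %d RNA replicates (background %s)\n",
              nrow(x$scores), ncol(x$scores), x$background_oligo_id))
  invisible(x)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled^2 = ((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2)`.
#'
#' @param x,y numeric samples of size >= 2.
#' @return numeric scalar; `+/-Inf` with a warning when the pooled SD is
#'   zero.
#' @export
cohens_d <- function(x, y) {
  stop_if_not(length(x) >= 2 && length(y) >= 2,
              "both samples need at least 2 values")
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) {
    warning("zero pooled SD; Cohen's d is infinite")
    return(sign(mean(x) - mean(y)) * Inf)
  }
  (mean(x) - mean(y)) / sp
}

# ---- design bookkeeping ---------------------------------------------------

.slot_matrix <- function(designs) {
  slot_cols <- grep("^slot[0-9]+$", names(designs), value = TRUE)
  stop_if_not(length(slot_cols) >= 1, "designs need slot columns")
  m <- as.matrix(designs[, slot_cols, drop = FALSE])
  rownames(m) <- designs$oligo_id
  m
}

.slot_key <- function(motif, orientation) paste(motif, orientation, sep = ":")

.slot_motif <- function(slots) sub(":(fwd|rev)$", "", slots)

# exclude control oligos from grammar analyses
.analysis_slots <- function(designs) {
  if (!is.null(designs$is_control)) designs <- designs[!designs$is_control, ]
  .slot_matrix(designs)
}

.untestable <- function(subject, reason) {
  data.frame(subject = subject, n_in = NA_integer_, n_out = NA_integer_,
             mean_in = NA_real_, mean_out = NA_real_, statistic = NA_real_,
             p_raw = NA_real_, alpha_bonferroni = NA_real_,
             cohens_d = NA_real_, significant = FALSE, testable = FALSE,
             reason = reason, stringsAsFactors = FALSE)
}


.group_values <- function(activity, ids, unit) {
  if (unit == "replicate") {
    v <- as.vector(activity$scores[ids, , drop = FALSE])
    v[!is.na(v)]
  } else {
    activity$oligo_mean[ids]
  }
}

.effect_row <- function(subject, x, y, test = c("welch", "wilcoxon"),
                        alpha_family = 0.05, m_tests = 1, d_min = 0.5,
                        use_d = TRUE, min_group = 2) {
  test <- match.arg(test)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < min_group || length(y) < min_group) {
    return(.untestable(subject, "insufficient group size"))
  }
  alpha <- alpha_family / m_tests
  if (test == "welch") {
    tt <- t.test(x, y, var.equal = FALSE)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  d <- suppressWarnings(cohens_d(x, y))
  sig <- p < alpha && (!use_d || (is.finite(d) && abs(d) > d_min))
  data.frame(subject = subject, n_in = length(x), n_out = length(y),
             mean_in = mean(x), mean_out = mean(y), statistic = stat,
             p_raw = p, alpha_bonferroni = alpha, cohens_d = d,
             significant = sig, testable = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

# ---- grammar tests --------------------------------------------------------

#' Effect of an oriented motif on activity
#'
#' Compares mean adjusted activity between oligos whose occupied slots
#' carry only the motif of interest (1-3 copies, all in the given
#' orientation) and oligos containing no instance of the motif in any
#' orientation. Two-sided Welch t-test with a Bonferroni-corrected alpha
#' and a Cohen's d magnitude gate.
#'
#' @param activity an `activity_matrix` from [activity()].
#' @param designs design/manifest table with slot columns (control oligos,
#'   flagged by an `is_control` column, are excluded).
#' @param motif,orientation the oriented motif (`orientation` `"fwd"` or
#'   `"rev"`).
#' @param alpha_family family-wise alpha (default 0.05).
#' @param m_tests Bonferroni denominator: number of tests in the family.
#' @param d_min Cohen's d magnitude threshold (default 0.5).
#' @param unit analyse per-oligo mean activities (`"oligo"`, default) or
#'   pooled replicate-level activities (`"replicate"`).
#' @return one-row data.frame: `subject`, `n_in`, `n_out`, `mean_in`,
#'   `mean_out`, `statistic`, `p_raw`, `alpha_bonferroni`, `cohens_d`,
#'   `significant`, `testable`, `reason`.
#' @export
motif_effect <- function(activity, designs, motif, orientation,
                         alpha_family = 0.05, m_tests = 1, d_min = 0.5,
                         unit = c("oligo", "replicate")) {
  unit <- match.arg(unit)
  slots <- .analysis_slots(designs)
  key <- .slot_key(motif, orientation)
  occ <- slots != "."
  n_occ <- rowSums(occ)
  only_key <- rowSums(occ & slots == key) == n_occ & n_occ >= 1 & n_occ <= 3
  has_motif <- rowSums(occ & .slot_motif(slots) == motif) > 0
  scored <- names(activity$oligo_mean)
  in_ids <- intersect(rownames(slots)[only_key], scored)
  out_ids <- intersect(rownames(slots)[!has_motif], scored)
  .effect_row(key, .group_values(activity, in_ids, unit),
              .group_values(activity, out_ids, unit), test = "welch",
              alpha_family = alpha_family, m_tests = m_tests, d_min = d_min)
}

#' Test every oriented motif in the library
#'
#' Runs [motif_effect()] for each motif x orientation present in the
#' designs, with the Bonferroni denominator set to the number of tests.
#'
#' @inheritParams motif_effect
#' @return data.frame of [motif_effect()] rows.
#' @export
motif_effects <- function(activity, designs, alpha_family = 0.05,
                          d_min = 0.5) {
  slots <- .analysis_slots(designs)
  keys <- sort(unique(slots[slots != "."]))
  res <- lapply(keys, function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    motif_effect(activity, designs, parts[1], parts[2],
                 alpha_family = alpha_family, m_tests = length(keys),
                 d_min = d_min)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Copy-number dose response of an oriented motif
#'
#' Ordinary least squares of mean adjusted activity on copy count over
#' oligos carrying only the motif of interest in the given orientation
#' (1-3 copies).
#'
#' @inheritParams motif_effect
#' @return one-row data.frame: `subject`, `slope`, `se`, `r_squared`, `p`
#'   (two-sided slope test), `ci_lo`, `ci_hi` (95% CI), `n`, `testable`.
#' @export
copy_number_fit <- function(activity, designs, motif, orientation) {
  slots <- .analysis_slots(designs)
  key <- .slot_key(motif, orientation)
  occ <- slots != "."
  n_occ <- rowSums(occ)
  only_key <- rowSums(occ & slots == key) == n_occ & n_occ >= 1 & n_occ <= 3
  am <- activity$oligo_mean
  ids <- intersect(rownames(slots)[only_key], names(am))
  copies <- n_occ[ids]
  y <- am[ids]
  keep <- !is.na(y)
  copies <- copies[keep]; y <- y[keep]
  if (length(unique(copies)) < 2 || length(y) < 3) {
    return(data.frame(subject = key, slope = NA_real_, se = NA_real_,
                      r_squared = NA_real_, p = NA_real_, ci_lo = NA_real_,
                      ci_hi = NA_real_, n = length(y), testable = FALSE,
                      stringsAsFactors = FALSE))
  }
  fit <- lm(y ~ copies)
  sm <- summary(fit)
  ci <- confint(fit, "copies", level = 0.95)
  data.frame(subject = key, slope = unname(coef(fit)["copies"]),
             se = sm$coefficients["copies", "Std. Error"],
             r_squared = sm$r.squared,
             p = sm$coefficients["copies", "Pr(>|t|)"],
             ci_lo = ci[1], ci_hi = ci[2], n = length(y), testable = TRUE,
             stringsAsFactors = FALSE)
}

#' Positional preference of an oriented motif
#'
#' Over oligos carrying exactly two distinct motifs in two occupied slots,
#' compares activity when the motif of interest sits in the
#' promoter-proximal occupied slot versus the promoter-distal one
#' (Wilcoxon rank-sum).
#'
#' @inheritParams motif_effect
#' @return one-row effect data.frame (see [motif_effect()]); the Cohen's d
#'   gate is not applied to this rank test.
#' @export
position_effect <- function(activity, designs, motif, orientation,
                            alpha_family = 0.05, m_tests = 1,
                            unit = c("oligo", "replicate")) {
  unit <- match.arg(unit)
  slots <- .analysis_slots(designs)
  key <- .slot_key(motif, orientation)
  occ <- slots != "."
  n_occ <- rowSums(occ)
  two_distinct <- n_occ == 2 &
    vapply(seq_len(nrow(slots)), function(i) {
      present <- slots[i, occ[i, ]]
      length(unique(.slot_motif(present))) == 2
    }, logical(1))
  has_key <- rowSums(occ & slots == key) > 0
  sel <- which(two_distinct & has_key)
  scored <- names(activity$oligo_mean)
  first_slot <- vapply(sel, function(i) {
    slots[i, which(occ[i, ])[1]] == key
  }, logical(1))
  ids <- rownames(slots)[sel]
  a_ids <- intersect(ids[first_slot], scored)
  b_ids <- intersect(ids[!first_slot], scored)
  .effect_row(key, .group_values(activity, a_ids, unit),
              .group_values(activity, b_ids, unit), test = "wilcoxon",
              alpha_family = alpha_family, m_tests = m_tests, use_d = FALSE)
}

#' Effect of an oriented motif pair on activity
#'
#' Compares oligos whose occupied slots comprise exactly the two oriented
#' motifs (both present, each 1-2 copies) against oligos lacking at least
#' one of the two. Welch t-test with Bonferroni alpha `alpha_family /
#' n_pairs` and a Cohen's d gate.
#'
#' @inheritParams motif_effect
#' @param motif1,orientation1,motif2,orientation2 the oriented pair; motif
#'   ids must be distinct.
#' @param n_pairs Bonferroni denominator: number of pairs tested.
#' @return one-row effect data.frame (see [motif_effect()]).
#' @export
pair_effect <- function(activity, designs, motif1, orientation1,
                        motif2, orientation2, alpha_family = 0.05,
                        n_pairs = 1, d_min = 0.5,
                        unit = c("oligo", "replicate")) {
  unit <- match.arg(unit)
  stop_if_not(motif1 != motif2, "pair motifs must be distinct")
  slots <- .analysis_slots(designs)
  k1 <- .slot_key(motif1, orientation1)
  k2 <- .slot_key(motif2, orientation2)
  occ <- slots != "."
  n_occ <- rowSums(occ)
  c1 <- rowSums(occ & slots == k1)
  c2 <- rowSums(occ & slots == k2)
  in_sel <- c1 >= 1 & c2 >= 1 & c1 <= 2 & c2 <= 2 & (c1 + c2) == n_occ
  out_sel <- c1 == 0 | c2 == 0
  scored <- names(activity$oligo_mean)
  in_ids <- intersect(rownames(slots)[in_sel], scored)
  out_ids <- intersect(rownames(slots)[out_sel], scored)
  .effect_row(paste(k1, k2, sep = ";"),
              .group_values(activity, in_ids, unit),
              .group_values(activity, out_ids, unit),
              test = "welch", alpha_family = alpha_family, m_tests = n_pairs,
              d_min = d_min)
}

#' Synergy test for a motif pair
#'
#' A pair is synergistic when (1) its Cohen's d magnitude is significantly
#' greater (one-sided Z-test on the standard large-sample SE of d) than
#' that of the stronger individual motif, and (2) the pair's mean in-group
#' activity exceeds the sum of the two individual mean in-group activities.
#'
#' @param pair_result row from [pair_effect()].
#' @param result_m1,result_m2 rows from [motif_effect()] for the two
#'   members.
#' @param alpha Z-test alpha (default 0.05).
#' @return list with `synergy`, `z`, `z_p`, `additive_excess` (pair mean
#'   minus sum of member means), `testable`.
#' @export
synergy_test <- function(pair_result, result_m1, result_m2, alpha = 0.05) {
  res <- list(synergy = FALSE, z = NA_real_, z_p = NA_real_,
              additive_excess = NA_real_, testable = FALSE)
  if (!isTRUE(pair_result$testable) || !isTRUE(result_m1$testable) ||
      !isTRUE(result_m2$testable)) {
    return(res)
  }
  if (!all(is.finite(c(pair_result$cohens_d, result_m1$cohens_d,
                       result_m2$cohens_d)))) {
    return(res)
  }
  se_d <- function(r) {
    sqrt((r$n_in + r$n_out) / (r$n_in * r$n_out) +
           r$cohens_d^2 / (2 * (r$n_in + r$n_out)))
  }
  best <- if (abs(result_m1$cohens_d) >= abs(result_m2$cohens_d))
    result_m1 else result_m2
  z <- (abs(pair_result$cohens_d) - abs(best$cohens_d)) /
    sqrt(se_d(pair_result)^2 + se_d(best)^2)
  z_p <- pnorm(z, lower.tail = FALSE)
  excess <- pair_result$mean_in - (result_m1$mean_in + result_m2$mean_in)
  list(synergy = (z_p < alpha) && (excess > 0), z = z, z_p = z_p,
       additive_excess = excess, testable = TRUE)
}

#' Order effect for an oriented motif pair
#'
#' Over oligos carrying exactly one copy of each of the two oriented
#' motifs and nothing else, compares activity when `motif1` precedes
#' `motif2` (reading from the core promoter) against the opposite order
#' (Wilcoxon rank-sum). Significant when the Bonferroni-corrected p-value
#' passes and the magnitude of the order-1/order-2 mean activity ratio
#' exceeds `ratio_min`.
#'
#' @inheritParams pair_effect
#' @param ratio_min mean-activity ratio magnitude threshold (default 2).
#' @param unit `"replicate"` (default) pools replicate-level activity
#'   scores, giving the rank test enough observations at the 3-per-order
#'   group sizes a 3-slot library produces; `"oligo"` uses per-oligo means.
#' @return one-row effect data.frame with an extra `ratio` column
#'   (`mean_in / mean_out`, order 1 over order 2).
#' @export
order_effect <- function(activity, designs, motif1, orientation1,
                         motif2, orientation2, alpha_family = 0.05,
                         n_pairs = 1, ratio_min = 2,
                         unit = c("replicate", "oligo")) {
  unit <- match.arg(unit)
  stop_if_not(motif1 != motif2, "pair motifs must be distinct")
  slots <- .analysis_slots(designs)
  k1 <- .slot_key(motif1, orientation1)
  k2 <- .slot_key(motif2, orientation2)
  occ <- slots != "."
  n_occ <- rowSums(occ)
  c1 <- rowSums(occ & slots == k1)
  c2 <- rowSums(occ & slots == k2)
  sel <- which(c1 == 1 & c2 == 1 & n_occ == 2)
  first_is_k1 <- vapply(sel, function(i) {
    slots[i, which(occ[i, ])[1]] == k1
  }, logical(1))
  scored <- names(activity$oligo_mean)
  ids <- rownames(slots)[sel]
  g1 <- intersect(ids[first_is_k1], scored)
  g2 <- intersect(ids[!first_is_k1], scored)
  row <- .effect_row(paste(k1, k2, sep = ">"),
                     .group_values(activity, g1, unit),
                     .group_values(activity, g2, unit),
                     test = "wilcoxon", alpha_family = alpha_family,
                     m_tests = n_pairs, use_d = FALSE)
  if (isTRUE(row$testable)) {
    if (row$mean_out == 0) {
      warning("order-2 mean activity is zero; ratio is infinite")
      row$ratio <- Inf
    } else {
      row$ratio <- row$mean_in / row$mean_out
    }
    row$significant <- row$p_raw < row$alpha_bonferroni &&
      abs(row$ratio) > ratio_min
  } else {
    row$ratio <- NA_real_
  }
  row
}
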