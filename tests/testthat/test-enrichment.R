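make_map <- function(links, genes) {
  tss <- data.frame(gene_id = genes, chrom = "chr1", tss = 0, strand = "+")
  structure(list(links = links, regions = NULL, tss = tss),
            class = "gene_region_map")
}

test_that("presence_table marks genes with at least one hit in a linked region", {
  links <- data.frame(
    gene_id = c("g1", "g1", "g2"),
    region_id = c("rP", "rD", "rX"),
    region_class = c("proximal", "distal", "proximal"))
  map <- make_map(links, c("g1", "g2", "g3"))
  hits <- data.frame(motif_id = c("m1", "m1", "m1", "m2"),
                     region_id = c("rP", "rP", "rP", "rD"))
  pt <- presence_table(map, hits, motifs = c("m1", "m2"))
  expect_true(pt["g1", "m1"])     # three hits in one region still count once
  expect_true(pt["g1", "m2"])
  expect_false(pt["g2", "m1"])    # regions but no hits
  expect_false(pt["g3", "m1"])    # no regions at all
  # class restriction
  ptp <- presence_table(map, hits, motifs = c("m1", "m2"),
                        region_class = "proximal")
  expect_false(ptp["g1", "m2"])   # m2's hit is distal
  # "both" is the union of the class tables; random instance vs nested loop
  set.seed(44)
  genes <- sprintf("g%02d", 1:15)
  linksr <- data.frame(
    gene_id = sample(genes, 40, replace = TRUE),
    region_id = sample(sprintf("r%02d", 1:20), 40, replace = TRUE),
    region_class = sample(c("proximal", "distal"), 40, replace = TRUE))
  hitsr <- data.frame(motif_id = sample(c("m1", "m2", "m3"), 25, replace = TRUE),
                      region_id = sample(sprintf("r%02d", 1:20), 25,
                                         replace = TRUE))
  mapr <- make_map(linksr, genes)
  ptr <- presence_table(mapr, hitsr, motifs = c("m1", "m2", "m3"))
  for (g in genes) {
    for (m in c("m1", "m2", "m3")) {
      expected <- FALSE
      for (i in which(linksr$gene_id == g)) {
        if (any(hitsr$motif_id == m & hitsr$region_id == linksr$region_id[i]))
          expected <- TRUE
      }
      expect_identical(unname(ptr[g, m]), expected)
    }
  }
})

test_that("pair_presence is the AND of the member columns", {
  links <- data.frame(gene_id = c("g1", "g1", "g2"),
                      region_id = c("rP", "rD", "rQ"),
                      region_class = c("proximal", "distal", "proximal"))
  map <- make_map(links, c("g1", "g2"))
  hits <- data.frame(motif_id = c("m1", "m2", "m1"),
                     region_id = c("rP", "rD", "rQ"))
  pt <- presence_table(map, hits, motifs = c("m1", "m2"))
  pp <- pair_presence(pt, c("m1", "m2"))
  expect_true(pp["g1"])            # m1 proximal, m2 distal, same gene
  expect_false(pp["g2"])           # only m1
  set.seed(4)
  mat <- matrix(runif(60) < 0.5, 20, 3,
                dimnames = list(sprintf("g%02d", 1:20), c("a", "b", "c")))
  expect_equal(unname(pair_presence(mat, c("a", "c"))),
               unname(mat[, "a"] & mat[, "c"]))
})

test_that("mc_test handles the degenerate extremes", {
  genes <- sprintf("g%03d", 1:120)
  target <- genes[1:20]
  comp <- genes[21:120]
  all_present <- setNames(rep(TRUE, 120), genes)
  r1 <- mc_test(all_present, target, comp, n_iter = 500, seed = 1)
  expect_equal(r1$p_value, 1)
  expect_equal(r1$fold_change, 1)
  expect_false(r1$enriched)

  only_target <- setNames(genes %in% target, genes)
  r2 <- mc_test(only_target, target, comp, n_iter = 500, seed = 2)
  expect_equal(r2$p_value, 0)
  expect_equal(r2$fold_change, Inf)
  expect_true(r2$enriched)

  none <- setNames(rep(FALSE, 120), genes)
  r3 <- mc_test(none, target, comp, n_iter = 200, seed = 3)
  expect_false(r3$enriched)
  expect_error(mc_test(all_present, target, comp, n_iter = 0), "n_iter")
  expect_error(mc_test(all_present, comp, target), "smaller")
})

test_that("mc_test matches the exact hypergeometric tail", {
  # 500 comparators at 30% presence; observed targets from 6..14
  set.seed(55)
  comp <- sprintf("c%03d", 1:500)
  target <- sprintf("t%02d", 1:22)
  pres_comp <- setNames(rep(FALSE, 500), comp)
  pres_comp[sample(500, 150)] <- TRUE
  for (obs in c(6, 10, 14)) {
    pres <- c(pres_comp, setNames(seq_along(target) <= obs, target))
    r <- mc_test(pres, target, comp, n_iter = 10000, seed = 100 + obs)
    exact <- phyper(obs - 1, 150, 350, 22, lower.tail = FALSE)
    expect_lt(abs(r$p_value - exact), 0.01)
  }
})

test_that("mc_test is reproducible under a fixed seed", {
  genes <- sprintf("g%03d", 1:200)
  pres <- setNames(seq_along(genes) %% 3 == 0, genes)
  a <- mc_test(pres, genes[1:10], genes[11:200], n_iter = 1000, seed = 7)
  b <- mc_test(pres, genes[1:10], genes[11:200], n_iter = 1000, seed = 7)
  expect_identical(a, b)
})

test_that("enrichment is anti-monotone in comparator presence", {
  set.seed(66)
  comp <- sprintf("c%03d", 1:200)
  target <- sprintf("t%02d", 1:15)
  base <- setNames(rep(FALSE, 200), comp)
  base[1:40] <- TRUE
  more <- base
  more[41:80] <- TRUE
  tvec <- setNames(rep(TRUE, 15), target)
  p_lo <- mc_test(c(base, tvec), target, comp, n_iter = 4000, seed = 8)$p_value
  p_hi <- mc_test(c(more, tvec), target, comp, n_iter = 4000, seed = 8)$p_value
  expect_gte(p_hi, p_lo)
})

test_that("the MC test is valid under the null (P(p < alpha) <= alpha + noise)", {
  set.seed(77)
  comp <- sprintf("c%03d", 1:300)
  n_sim <- 200
  rej05 <- 0
  for (i in seq_len(n_sim)) {
    pres <- setNames(runif(300) < runif(1, 0.1, 0.7), comp)
    targ <- sample(comp, 22)
    rest <- setdiff(comp, targ)
    r <- mc_test(pres, targ, rest, n_iter = 400, seed = 1000 + i)
    if (r$p_value < 0.05) rej05 <- rej05 + 1
  }
  # conservative discrete test: rejection rate must not exceed the level
  # (3 binomial SEs of slack on 200 simulations)
  expect_lte(rej05 / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("enumerate_pairs produces the unordered and cross universes", {
  ids <- c("a", "b", "c")
  un <- enumerate_pairs(ids)
  expect_equal(nrow(un), 3)
  cr <- enumerate_pairs(ids, mode = "cross")
  expect_equal(nrow(cr), 9)
  expect_true(any(cr$motif1 == "a" & cr$motif2 == "a"))
})

test_that("expression_filter_tfbs applies the all-components rule", {
  agg <- c(TF1 = 500, TF2 = 100, TF3 = 300)
  mg <- list(mono_lo = "TF2", mono_hi = "TF1", dimer = c("TF1", "TF2"),
             dimer_hi = c("TF1", "TF3"))
  out <- expression_filter_tfbs(names(mg), mg, agg, threshold = 237.04)
  expect_setequal(out, c("mono_hi", "dimer_hi"))
  expect_warning(
    out2 <- expression_filter_tfbs(c("mono_hi", "orphan"), mg, agg, 237.04),
    "retained")
  expect_true("orphan" %in% out2)
})

test_that("rank_pairs sums the two ranks with lexicographic ties", {
  res <- data.frame(subject = c("A;B", "C;D"), observed = c(20, 10),
                    null_mean = c(1, 5))
  rk <- rank_pairs(res)
  expect_equal(rk$subject[1], "A;B")

  tie <- data.frame(subject = c("z;z", "a;a"), observed = c(5, 5),
                    null_mean = c(2, 2))
  expect_equal(rank_pairs(tie)$subject, c("a;a", "z;z"))

  set.seed(88)
  rnd <- data.frame(subject = sprintf("p%02d", 1:20),
                    observed = sample(0:22, 20, replace = TRUE),
                    null_mean = runif(20, 0, 8))
  rk2 <- rank_pairs(rnd)
  oracle_rank <- rank(-rnd$observed) + rank(rnd$null_mean)
  expect_equal(rk2$subject,
               rnd$subject[order(oracle_rank, rnd$subject)])
})

test_that("select_candidates walks the ranked lists with archetype exclusion", {
  arch <- c(T1 = "arch1", T2 = "arch1", T3 = "arch2", T4 = "arch3",
            T5 = "arch4")
  tt <- data.frame(motif1 = c("T1", "T2", "T3"),
                   motif2 = c("T2", "T4", "T5"))
  # T1 (arch1), T2 skipped (arch1 taken); then T2 skipped again, T4; T3, T5
  got <- select_candidates(tt,
                           data.frame(motif1 = character(0),
                                      motif2 = character(0)),
                           arch, n_tfbs = 3, n_novel = 0)
  expect_equal(got$tfbs, c("T1", "T4", "T3"))

  # n_tfbs = 1 picks the first-ranked pair's first motif
  got1 <- select_candidates(tt, tt[0, ], arch, n_tfbs = 1, n_novel = 0)
  expect_equal(got1$tfbs, "T1")

  # novel walk restricted to pairs containing a selected TFBS
  tn <- data.frame(motif1 = c("T9", "T1", "T4", "T1"),
                   motif2 = c("N1", "N2", "N3", "N2"))
  expect_warning(
    got2 <- select_candidates(tt, tn, arch, n_tfbs = 2, n_novel = 3),
    "exhausted")
  expect_equal(got2$novel, c("N2", "N3"))   # N1's TFBS was never selected

  # step-by-step simulation oracle on a randomized instance
  set.seed(99)
  tfbs_ids <- sprintf("T%02d", 1:12)
  archr <- setNames(sample(sprintf("a%d", 1:6), 12, replace = TRUE), tfbs_ids)
  ttr <- data.frame(motif1 = sample(tfbs_ids, 30, replace = TRUE),
                    motif2 = sample(tfbs_ids, 30, replace = TRUE))
  ttr <- ttr[ttr$motif1 != ttr$motif2, ]
  gotr <- suppressWarnings(
    select_candidates(ttr, ttr[0, ], archr, n_tfbs = 4, n_novel = 0))
  sel <- character(0); used <- character(0)
  for (i in seq_len(nrow(ttr))) {
    for (m in c(ttr$motif1[i], ttr$motif2[i])) {
      if (length(sel) >= 4 || m %in% sel || archr[[m]] %in% used) next
      sel <- c(sel, m); used <- c(used, archr[[m]])
    }
  }
  expect_equal(gotr$tfbs, sel)
})

test_that("representative_site prefers frequency, then score, then lexicographic", {
  hits <- data.frame(motif_id = "m",
                     match = c("ACGT", "ACGT", "ACGT", "TGCA"),
                     score = c(5, 6, 5, 20))
  expect_equal(representative_site("m", hits), "ACGT")

  tie <- data.frame(motif_id = "m",
                    match = c("AAAA", "AAAA", "CCCC", "CCCC"),
                    score = c(12, 11, 10, 9))
  expect_equal(representative_site("m", tie), "AAAA")

  tie2 <- data.frame(motif_id = "m",
                     match = c("GGGG", "GGGG", "CCCC", "CCCC"),
                     score = c(10, 8, 10, 8))
  expect_equal(representative_site("m", tie2), "CCCC")
  expect_error(representative_site("x", hits), "no hits")

  set.seed(101)
  sites <- sprintf("S%02d", 1:8)
  rnd <- data.frame(motif_id = "m",
                    match = sample(sites, 60, replace = TRUE),
                    score = round(runif(60, 5, 15), 3))
  got <- representative_site("m", rnd)
  tab <- table(rnd$match)
  cand <- names(tab)[tab == max(tab)]
  best <- vapply(cand, function(s) max(rnd$score[rnd$match == s]), numeric(1))
  cand <- cand[best == max(best)]
  expect_equal(got, sort(cand)[1])
})
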