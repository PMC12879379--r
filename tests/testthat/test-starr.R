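test_that("qc_filter applies the DNA floor and RNA detectability rules", {
  dna <- matrix(10, nrow = 3, ncol = 8,
                dimnames = list(c("o1", "o2", "o3"), NULL))
  rna <- matrix(c(1, 1, 0,   0, 0, 0,   5, 5, 5), nrow = 3, byrow = TRUE,
                dimnames = list(c("o1", "o2", "o3"), NULL))
  expect_setequal(qc_filter(dna, rna), c("o1", "o3"))

  dna2 <- dna; dna2["o3", 4] <- 9        # one replicate below the floor
  expect_setequal(qc_filter(dna2, rna), "o1")

  # random tables against a predicate-loop oracle
  set.seed(61)
  ids <- sprintf("o%03d", 1:50)
  dnar <- matrix(rpois(400, 12), 50, 8, dimnames = list(ids, NULL))
  rnar <- matrix(rpois(150, 1), 50, 3, dimnames = list(ids, NULL))
  got <- qc_filter(dnar, rnar)
  for (o in ids) {
    keep <- all(dnar[o, ] >= 10) && sum(rnar[o, ] > 0) >= 2
    expect_equal(o %in% got, keep, info = o)
  }
  expect_error(qc_filter(dnar * 0, rnar), "no oligo")
})

test_that("cpm columns sum to 1e6 exactly", {
  one <- matrix(5, 1, 1, dimnames = list("o1", "r1"))
  expect_equal(cpm(one)[1, 1], 1e6)
  set.seed(62)
  m <- matrix(rpois(60, 40), 20, 3,
              dimnames = list(sprintf("o%02d", 1:20), c("a", "b", "c")))
  n <- cpm(m)
  expect_equal(unname(colSums(n)), rep(1e6, 3))
  expect_equal(n[3, 2], m[3, 2] / sum(m[, 2]) * 1e6)
  m0 <- m; m0[, 2] <- 0
  expect_error(cpm(m0), "zero total")
})

test_that("activity pins the background oligo at zero and doubles to +1", {
  ids <- c("BG", "o1", "o2")
  dna <- matrix(100, 3, 4, dimnames = list(ids, NULL))
  dna_cpm <- cpm(dna)
  # o1's RNA is twice the background's DNA-relative rate in every replicate
  rna <- matrix(c(10, 10, 10,  20, 20, 20,  5, 5, 5), nrow = 3, byrow = TRUE,
                dimnames = list(ids, paste0("R", 1:3)))
  act <- activity(cpm(dna), cpm(rna), "BG")
  expect_equal(unname(act$scores["BG", ]), rep(0, 3))
  expect_equal(unname(act$oligo_mean["o1"]), 1)
  expect_equal(unname(act$oligo_mean["o2"]), -1)

  # formula oracle on random counts (zeros give missing scores)
  set.seed(63)
  idsr <- c("BG", sprintf("o%02d", 1:30))
  dnar <- matrix(rpois(31 * 8, 200), 31, 8, dimnames = list(idsr, NULL))
  rnar <- matrix(rpois(31 * 3, 3), 31, 3,
                 dimnames = list(idsr, paste0("R", 1:3)))
  rnar["BG", ] <- pmax(rnar["BG", ], 1)
  actr <- activity(cpm(dnar), cpm(rnar), "BG")
  dmean <- rowMeans(cpm(dnar))
  rcpm <- cpm(rnar)
  for (o in sample(idsr, 8)) {
    for (r in 1:3) {
      if (rnar[o, r] == 0) {
        expect_true(is.na(actr$scores[o, r]))
      } else {
        expect_equal(actr$scores[o, r],
                     unname(log2(rcpm[o, r] / dmean[o]) -
                              log2(rcpm["BG", r] / dmean["BG"])))
      }
    }
  }

  # replicate-wise scaling invariance: multiplying all RNA counts of one
  # replicate by a constant cancels through CPM + background subtraction
  rnar2 <- rnar; rnar2[, 2] <- rnar2[, 2] * 7
  actr2 <- activity(cpm(dnar), cpm(rnar2), "BG")
  expect_equal(actr$scores, actr2$scores)
})

test_that("cohens_d follows the pooled-SD formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x), 0)
  y <- c(0, 1, 2, 3)
  # x = y + 1 elementwise, both sample SDs equal
  expect_equal(cohens_d(x, y), 1 / sd(x))
  set.seed(64)
  a <- rnorm(15); b <- rnorm(9, 1)
  sp <- sqrt((14 * var(a) + 8 * var(b)) / 22)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_warning(d <- cohens_d(c(1, 1), c(0, 0)), "zero pooled")
  expect_equal(d, Inf)
})

test_that("motif_effect groups match hand enumeration on a toy library", {
  designs <- enumerate_designs(c("A", "B", "C"), n_slots = 3)
  slots <- as.matrix(designs[, c("slot1", "slot2", "slot3")])
  # fabricate an activity object covering all oligos (tiny noise so the
  # Welch test is defined)
  set.seed(60)
  am <- setNames(rnorm(nrow(designs), 0, 1e-6), designs$oligo_id)
  act <- structure(list(oligo_mean = am), class = "activity_matrix")
  # in-group for A:fwd: occupied slots all A:fwd, 1-3 copies
  in_hand <- designs$oligo_id[apply(slots, 1, function(s) {
    occ <- s[s != "."]
    length(occ) >= 1 && all(occ == "A:fwd")
  })]
  out_hand <- designs$oligo_id[apply(slots, 1, function(s) {
    !any(s %in% c("A:fwd", "A:rev"))
  })]
  expect_equal(length(in_hand), 7)   # 2^3 - 1 placements
  got <- motif_effect(act, designs, "A", "fwd")
  expect_equal(got$n_in, length(in_hand))
  expect_equal(got$n_out, length(out_hand))
})

test_that("planted oriented-motif effects are recovered with correct sign", {
  # one planted motif per library: the out-group ("no instance of the
  # motif") absorbs any other planted effect, so shifts are estimated
  # against an effect-free companion motif
  fixA <- toy_starr(motifs = c("m1", "m2"),
                    effects = list(beta = c("m1:fwd" = 1)), seed = 71)
  resA <- motif_effects(fixA$act, fixA$designs)
  r1 <- resA[resA$subject == "m1:fwd", ]
  r0 <- resA[resA$subject == "m1:rev", ]
  expect_true(r1$significant)
  expect_gt(r1$cohens_d, 0)
  expect_equal(r1$mean_in - r1$mean_out, 1, tolerance = 0.1)
  expect_false(r0$significant)

  fixB <- toy_starr(motifs = c("m1", "m2"),
                    effects = list(beta = c("m2:rev" = -0.5)), seed = 79)
  r2 <- motif_effect(fixB$act, fixB$designs, "m2", "rev", m_tests = 4)
  expect_true(r2$significant)
  expect_lt(r2$cohens_d, 0)
  expect_equal(r2$mean_in - r2$mean_out, -0.5, tolerance = 0.1)
})

test_that("motif_effect controls type I error with no planted effect", {
  rejections <- 0
  n_sim <- 60
  for (s in seq_len(n_sim)) {
    fix <- toy_starr(motifs = c("m1", "m2"), effects = list(),
                     seed = 700 + s, depth = 200)
    r <- motif_effect(fix$act, fix$designs, "m1", "fwd",
                      alpha_family = 0.05, m_tests = 1, d_min = 0)
    if (isTRUE(r$significant)) rejections <- rejections + 1
  }
  expect_lte(rejections / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("copy_number_fit recovers a planted per-copy slope", {
  effects <- list(beta = c("m1:fwd" = 0.5), slope = c("m1:fwd" = -0.8))
  fix <- toy_starr(motifs = c("m1", "m2"), effects = effects, seed = 72)
  fit <- copy_number_fit(fix$act, fix$designs, "m1", "fwd")
  expect_true(fit$testable)
  expect_true(fit$ci_lo <= -0.8 && -0.8 <= fit$ci_hi)
  expect_gt(fit$r_squared, 0.8)

  # exact line: 3 points on a line give r^2 = 1, slope recovered exactly
  designs <- enumerate_designs("m1", n_slots = 3)
  slots <- as.matrix(designs[, c("slot1", "slot2", "slot3")])
  copies <- rowSums(slots == "m1:fwd") * (rowSums(slots != ".") ==
                                            rowSums(slots == "m1:fwd"))
  am <- setNames(2 - 0.3 * copies, designs$oligo_id)
  am[copies == 0] <- NA
  am[rowSums(slots != ".") == 0] <- 0
  act <- structure(list(oligo_mean = am), class = "activity_matrix")
  fit2 <- copy_number_fit(act, designs, "m1", "fwd")
  expect_equal(fit2$slope, -0.3)
  expect_equal(fit2$r_squared, 1)
  # constant activities: zero slope
  am3 <- setNames(rep(1.5, nrow(designs)), designs$oligo_id)
  act3 <- structure(list(oligo_mean = am3), class = "activity_matrix")
  fit3 <- copy_number_fit(act3, designs, "m1", "fwd")
  expect_equal(fit3$slope, 0)
})

test_that("position_effect detects a planted slot preference", {
  # delta: m1:fwd activates only when promoter-proximal (slot 1)
  effects <- list(delta = c("m1:fwd@1" = 1.2))
  fix <- toy_starr(motifs = c("m1", "m2"), effects = effects, seed = 73)
  r <- position_effect(fix$act, fix$designs, "m1", "fwd")
  expect_true(r$testable)
  expect_true(r$significant)
  expect_gt(r$mean_in, r$mean_out)

  # no positional term: not significant in a null library
  fix0 <- toy_starr(motifs = c("m1", "m2"), effects = list(), seed = 74)
  r0 <- position_effect(fix0$act, fix0$designs, "m1", "fwd")
  expect_false(r0$significant)

  # group membership by hand on the toy library
  designs <- fix$designs
  slots <- as.matrix(designs[, c("slot1", "slot2", "slot3")])
  sel <- apply(slots, 1, function(s) {
    occ <- s[s != "."]
    length(occ) == 2 &&
      length(unique(sub(":(fwd|rev)$", "", occ))) == 2 &&
      "m1:fwd" %in% occ
  })
  first <- apply(slots, 1, function(s) {
    occ <- s[s != "."]
    length(occ) >= 1 && occ[1] == "m1:fwd"
  })
  expect_equal(r$n_in + r$n_out, sum(sel))
  expect_equal(r$n_in, sum(sel & first))
})

test_that("pair_effect in-group is exactly the two-motif 1-2 copy oligos", {
  designs <- enumerate_designs(c("A", "B", "C"), n_slots = 3)
  slots <- as.matrix(designs[, c("slot1", "slot2", "slot3")])
  am <- setNames(rnorm(nrow(designs), 0, 1e-6), designs$oligo_id)
  act <- structure(list(oligo_mean = am), class = "activity_matrix")
  r <- pair_effect(act, designs, "A", "fwd", "B", "rev")
  in_hand <- apply(slots, 1, function(s) {
    occ <- s[s != "."]
    c1 <- sum(occ == "A:fwd"); c2 <- sum(occ == "B:rev")
    c1 >= 1 && c2 >= 1 && c1 <= 2 && c2 <= 2 && c1 + c2 == length(occ)
  })
  out_hand <- apply(slots, 1, function(s) {
    occ <- s[s != "."]
    sum(occ == "A:fwd") == 0 || sum(occ == "B:rev") == 0
  })
  expect_equal(r$n_in, sum(in_hand))
  expect_equal(r$n_out, sum(out_hand))
  expect_error(pair_effect(act, designs, "A", "fwd", "A", "rev"), "distinct")
})

test_that("pair_effect detects a planted interaction", {
  effects <- list(beta = c("m1:fwd" = 0.3, "m2:fwd" = 0.3),
                  gamma = c("m1:fwd;m2:fwd" = 1))
  fix <- toy_starr(motifs = c("m1", "m2"), effects = effects, seed = 75)
  r <- pair_effect(fix$act, fix$designs, "m1", "fwd", "m2", "fwd")
  expect_true(r$significant)
  expect_gt(r$cohens_d, 0)
})

test_that("synergy_test separates interaction from dominance", {
  # same samples for pair and best single: Z = 0, no synergy
  base <- data.frame(n_in = 10, n_out = 50, mean_in = 1, mean_out = 0,
                     cohens_d = 2, testable = TRUE)
  self <- synergy_test(base, base, transform(base, mean_in = 0),
                       alpha = 0.05)
  expect_equal(self$z, 0)
  expect_false(self$synergy)

  # planted gamma large, betas small: synergy detected
  effects <- list(beta = c("m1:fwd" = 0.1, "m2:fwd" = 0.1),
                  gamma = c("m1:fwd;m2:fwd" = 1.2))
  fix <- toy_starr(motifs = c("m1", "m2"), effects = effects, seed = 76)
  rp <- pair_effect(fix$act, fix$designs, "m1", "fwd", "m2", "fwd")
  r1 <- motif_effect(fix$act, fix$designs, "m1", "fwd")
  r2 <- motif_effect(fix$act, fix$designs, "m2", "fwd")
  syn <- synergy_test(rp, r1, r2)
  expect_true(syn$testable)
  expect_true(syn$synergy)

  # dominant single motif, no interaction: no synergy in most simulations
  n_syn <- 0
  n_sim <- 40
  for (s in seq_len(n_sim)) {
    eff0 <- list(beta = c("m1:fwd" = 0.5))
    f0 <- toy_starr(motifs = c("m1", "m2"), effects = eff0, seed = 7000 + s)
    rp0 <- pair_effect(f0$act, f0$designs, "m1", "fwd", "m2", "fwd")
    r10 <- motif_effect(f0$act, f0$designs, "m1", "fwd")
    r20 <- motif_effect(f0$act, f0$designs, "m2", "fwd")
    s0 <- synergy_test(rp0, r10, r20)
    if (isTRUE(s0$synergy)) n_syn <- n_syn + 1
  }
  expect_lte(n_syn / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("order_effect needs both significance and a 2-fold mean ratio", {
  # planted order preference via position deltas on one member of the pair
  # (magnitudes chosen so the order-1/order-2 mean ratio clears 2)
  effects <- list(delta = c("m1:fwd@1" = 2, "m1:fwd@2" = 0.3,
                            "m1:fwd@3" = 0.3))
  fix <- toy_starr(motifs = c("m1", "m2"), effects = effects, seed = 77)
  r <- order_effect(fix$act, fix$designs, "m1", "fwd", "m2", "fwd")
  expect_true(r$testable)
  expect_true(r$significant)

  # symmetric effects: not significant
  fix0 <- toy_starr(motifs = c("m1", "m2"),
                    effects = list(beta = c("m1:fwd" = 0.4, "m2:fwd" = 0.4)),
                    seed = 78)
  r0 <- order_effect(fix0$act, fix0$designs, "m1", "fwd", "m2", "fwd")
  expect_false(r0$significant)

  # group membership by hand
  slots <- as.matrix(fix$designs[, c("slot1", "slot2", "slot3")])
  hand <- apply(slots, 1, function(s) {
    occ <- s[s != "."]
    length(occ) == 2 && sum(occ == "m1:fwd") == 1 && sum(occ == "m2:fwd") == 1
  })
  # replicate-level unit: 3 RNA replicates per qualifying oligo
  expect_equal(r$n_in + r$n_out, 3 * sum(hand))
})
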