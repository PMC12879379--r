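# Shared fixture builders; everything is generated in code under fixed seeds.

random_ppm <- function(L = 8, motif_id = "rand", seed = NULL,
                       concentration = 1) {
  regulogic:::with_seed(seed, {
    m <- matrix(rgamma(4 * L, shape = concentration), nrow = 4)
    m <- sweep(m, 2, colSums(m), "/")
    rownames(m) <- c("A", "C", "G", "T")
    ppm(motif_id, m)
  })
}

# a sharp (informative) random PPM whose consensus is a strong site
sharp_ppm <- function(L = 10, motif_id = "sharp", seed = NULL) {
  regulogic:::with_seed(seed, {
    cons <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    m <- matrix(0.04, nrow = 4, ncol = L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(L)) m[cons[j], j] <- 0.88
    ppm(motif_id, m)
  })
}

random_seq <- function(n, seed = NULL) {
  regulogic:::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  })
}

# brute-force per-column Pearson with the constant-column convention,
# exhaustive over offsets and strands: oracle for motif_similarity
oracle_similarity <- function(a, b, min_overlap) {
  colr <- function(x, y) {
    if (sd(x) < 1e-12 || sd(y) < 1e-12) return(as.numeric(max(abs(x - y)) < 1e-9))
    cor(x, y)
  }
  best <- -Inf
  for (bm in list(b$matrix, rc_ppm(b)$matrix)) {
    la <- ncol(a$matrix); lb <- ncol(bm)
    for (d in -(lb):(la)) {
      js <- seq(max(1, 1 + d), min(la, lb + d))
      if (length(js) < min_overlap) next
      s <- mean(vapply(js, function(j) colr(a$matrix[, j], bm[, j - d]),
                       numeric(1)))
      if (s > best) best <- s
    }
  }
  best
}

# exact PWM score tail by enumerating all 4^L sequences
oracle_tail <- function(pwm, score) {
  L <- ncol(pwm$matrix)
  grid <- do.call(expand.grid, rep(list(1:4), L))
  scores <- apply(grid, 1, function(idx)
    sum(pwm$matrix[cbind(idx, seq_len(L))]))
  probs <- apply(grid, 1, function(idx) prod(pwm$background[idx]))
  vapply(score, function(s) sum(probs[scores >= s]), numeric(1))
}

# per-window brute-force scan oracle (both strands, no N handling needed
# when sequences are pure ACGT)
oracle_scan <- function(pwm, s, p_thresh, granularity = 1e-3) {
  L <- ncol(pwm$matrix)
  dist <- regulogic:::score_distribution(pwm, granularity = granularity)
  dmat <- round(pwm$matrix / granularity)
  n <- nchar(s) - L + 1
  rows <- list()
  for (i in seq_len(max(n, 0))) {
    win <- substr(s, i, i + L - 1)
    for (str in c("+", "-")) {
      w <- if (str == "-") revcomp(win) else win
      idx <- match(strsplit(w, "")[[1]], c("A", "C", "G", "T"))
      sc <- sum(pwm$matrix[cbind(idx, seq_len(L))])
      p <- regulogic:::.tail_at(dist, sum(dmat[cbind(idx, seq_len(L))]))
      if (p <= p_thresh) {
        rows[[length(rows) + 1]] <- data.frame(
          offset = i - 1L, strand = str, score = sc, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, rows)
}

# small three-motif library with rendered sequences and simulated counts
toy_starr <- function(motifs = c("m1", "m2"), effects = list(), seed = 1,
                      depth = 500, dispersion = 0.01, ...) {
  designs <- enumerate_designs(motifs, n_slots = 3)
  counts <- synth_starr(designs, effects = effects, depth = depth,
                        dispersion = dispersion, seed = seed, ...)
  keep <- qc_filter(counts$dna, counts$rna)
  act <- activity(cpm(counts$dna)[keep, , drop = FALSE],
                  cpm(counts$rna)[keep, , drop = FALSE],
                  designs$oligo_id[designs$is_background])
  list(designs = designs, counts = counts, act = act)
}
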