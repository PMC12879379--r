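# Synthetic-data generators: every pipeline input with known ground truth.
# All generators are pure functions of their seed and parameters.

#' Simulate a normalized expression matrix with planted specific genes
#'
#' Gene baselines are log-normal; counts are negative binomial around the
#' baseline. Planted genes have their mean multiplied by `fold` in target
#' samples and divided by `fold` in background samples.
#'
#' @param n_genes total genes (default 2000).
#' @param n_target,n_background samples per group (defaults 10 and 20).
#' @param n_planted number of planted target-specific genes (default 20).
#' @param fold planted fold change (> 1; default 8).
#' @param dispersion negative-binomial dispersion (default 0.2, a typical
#'   bulk RNA-seq spread).
#' @param base_meanlog,base_sdlog log-normal baseline parameters.
#' @param seed RNG seed.
#' @return list with `expr` (matrix), `sample_group`, and `truth`
#'   (`planted_genes`, `fold`, `seed`).
#' @export
synth_expression <- function(n_genes = 2000, n_target = 10,
                             n_background = 20, n_planted = 20, fold = 8,
                             dispersion = 0.2, base_meanlog = log(100),
                             base_sdlog = 1, seed = NULL) {
  stop_if_not(fold >= 1, "fold must be >= 1")
  stop_if_not(n_planted <= n_genes, "more planted genes than genes")
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    samples <- c(sprintf("T%02d", seq_len(n_target)),
                 sprintf("B%02d", seq_len(n_background)))
    grp <- setNames(rep(c("target", "background"),
                        c(n_target, n_background)), samples)
    base <- rlnorm(n_genes, base_meanlog, base_sdlog)
    planted <- genes[seq_len(n_planted)]
    mu <- matrix(base, n_genes, n_target + n_background,
                 dimnames = list(genes, samples))
    mu[planted, grp == "target"] <- mu[planted, grp == "target"] * fold
    mu[planted, grp == "background"] <- mu[planted, grp == "background"] / fold
    size <- 1 / dispersion
    expr <- matrix(rnbinom(length(mu), mu = mu, size = size),
                   nrow = n_genes, dimnames = dimnames(mu))
    list(expr = expr, sample_group = grp,
         truth = list(planted_genes = planted, fold = fold, seed = seed))
  })
}

#' Simulate a regulatory genome with planted motif sites
#'
#' Each gene lives on its own synthetic chromosome with a TSS, one
#' promoter-overlapping proximal region and `n_distal` distal regions; a
#' chromatin loop connects the proximal region's bin to each distal
#' region's bin. Consensus sites of the planted motifs are written into
#' region sequences with a gene-class-dependent probability
#' (`odds["target"]` for the first `n_target` genes, `odds["comparator"]`
#' for the rest).
#'
#' @param n_genes number of genes (default 50).
#' @param n_target genes of the target class (default 10).
#' @param n_distal distal regions per gene (default 2).
#' @param region_len region length in bp (default 200).
#' @param motifs list of [ppm]s (or named character site sequences) to
#'   plant.
#' @param odds named numeric: per-region site probability for `target` and
#'   `comparator` genes.
#' @param seed RNG seed.
#' @return list with `sequences` (named by region id), `regions`, `tss`,
#'   `interactions`, `sample_group` of genes (`gene_class`), and `truth`
#'   (`site_placements` data.frame, `odds`, `seed`).
#' @export
synth_regulatory_genome <- function(n_genes = 50, n_target = 10,
                                    n_distal = 2, region_len = 200,
                                    motifs = list(),
                                    odds = c(target = 0.8, comparator = 0.1),
                                    seed = NULL) {
  stop_if_not(all(odds >= 0 & odds <= 1), "odds must be probabilities")
  sites <- if (is.character(motifs)) motifs else
    setNames(vapply(motifs, consensus, character(1)),
             vapply(motifs, `[[`, "", "motif_id"))
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    gene_class <- setNames(rep(c("target", "comparator"),
                               c(n_target, n_genes - n_target)), genes)
    tss_pos <- 5000L
    regions <- list(); seqs <- list(); loops <- list(); placements <- list()
    for (gi in seq_len(n_genes)) {
      chrom <- sprintf("chr_%s", genes[gi])
      # proximal region centred on the TSS, distal regions downstream
      starts <- c(tss_pos - region_len %/% 2L,
                  tss_pos + 20000L * seq_len(n_distal))
      classes <- c("proximal", rep("distal", n_distal))
      for (ri in seq_along(starts)) {
        rid <- sprintf("%s:%d-%d", chrom, starts[ri],
                       starts[ri] + region_len)
        regions[[rid]] <- data.frame(
          chrom = chrom, start = starts[ri], end = starts[ri] + region_len,
          region_id = rid, stringsAsFactors = FALSE)
        s <- paste(sample(DNA_BASES, region_len, replace = TRUE),
                   collapse = "")
        for (m in names(sites)) {
          if (runif(1) < odds[[gene_class[gi]]]) {
            site <- sites[[m]]
            off <- sample.int(region_len - nchar(site) + 1, 1) - 1L
            strand <- sample(c("+", "-"), 1)
            put <- if (strand == "-") revcomp(site) else site
            substr(s, off + 1, off + nchar(site)) <- put
            placements[[length(placements) + 1L]] <- data.frame(
              region_id = rid, motif_id = m, offset = off, strand = strand,
              stringsAsFactors = FALSE)
          }
        }
        seqs[[rid]] <- s
        if (classes[ri] == "distal") {
          # loop: promoter bin <-> distal bin (5 kb bins around each)
          loops[[length(loops) + 1L]] <- data.frame(
            chrom1 = chrom, start1 = tss_pos - 2500L, end1 = tss_pos + 2500L,
            chrom2 = chrom, start2 = starts[ri] - 2500L,
            end2 = starts[ri] + 2500L,
            name = sprintf("loop_%s_%d", genes[gi], ri - 1L), score = 1,
            stringsAsFactors = FALSE)
        }
      }
    }
    tss <- data.frame(gene_id = genes,
                      chrom = sprintf("chr_%s", genes),
                      tss = tss_pos, strand = "+", stringsAsFactors = FALSE)
    list(sequences = unlist(seqs),
         regions = do.call(rbind, c(regions, list(make.row.names = FALSE))),
         tss = tss,
         interactions = do.call(rbind, loops),
         gene_class = gene_class,
         truth = list(
           site_placements = if (length(placements) > 0)
             do.call(rbind, placements) else
               data.frame(region_id = character(0), motif_id = character(0),
                          offset = integer(0), strand = character(0)),
           odds = odds, seed = seed))
  })
}

#' Simulate STARR-seq count tables for a designed library
#'
#' DNA counts are negative binomial around a per-oligo representation
#' (log-normal spread times `depth`). Expected RNA rates are proportional
#' to the realized mean DNA CPM times `2^eta(oligo)`, where `eta` collects
#' the planted log2 effects: each distinct oriented motif present
#' contributes its `beta` once plus `slope * (copies - 1)`; each unordered
#' oriented pair present contributes `gamma`; each occupied position
#' contributes `delta` for its oriented motif, with positions counted in
#' promoter-relative packed order (first occupied slot = position 1). The
#' motif-free background oligo has `eta = 0`.
#'
#' @param designs design/manifest table with slot columns (see
#'   [enumerate_designs()]).
#' @param effects list with optional named numeric components: `beta`
#'   (names `"motif:orient"`), `slope` (per-copy increments, same names),
#'   `gamma` (names `"key1;key2"`, keys sorted), `delta` (names
#'   `"motif:orient@k"` with `k` the promoter-relative occupied position).
#' @param depth mean DNA count per oligo per replicate (default 500).
#' @param dispersion negative-binomial dispersion of DNA and RNA counts.
#'   The default 0.01 reproduces the tight replicate agreement of a clean
#'   reporter assay (CPM correlations ~0.98); raise it, or use
#'   `rep_effect_sd`, for noisier cell contexts.
#' @param abundance_sdlog log-normal SD of per-oligo library
#'   representation (default 0.3).
#' @param n_rna_reps,n_dna_reps replicate counts (defaults 3 and 8).
#' @param rep_effect_sd SD of an extra per-oligo, per-RNA-replicate
#'   log2-scale random effect (default 0; emulates heterogeneous host
#'   cells with low replicate correlation).
#' @param seed RNG seed.
#' @return list with `dna`, `rna` (count matrices), and `truth` (`eta`,
#'   `effects`, `seed`).
#' @export
synth_starr <- function(designs, effects = list(), depth = 500,
                        dispersion = 0.01, abundance_sdlog = 0.3,
                        n_rna_reps = 3, n_dna_reps = 8, rep_effect_sd = 0,
                        seed = NULL) {
  slots <- .slot_matrix(designs)
  for (comp in c("beta", "slope", "gamma", "delta")) {
    vals <- effects[[comp]]
    if (!is.null(vals)) {
      stop_if_not(!is.null(names(vals)) && all(names(vals) != ""),
                  sprintf("effects$%s must be named", comp))
    }
  }
  eff <- function(comp, key) {
    v <- effects[[comp]]
    if (is.null(v)) return(rep(0, length(key)))
    out <- unname(v[key])
    out[is.na(out)] <- 0
    out
  }
  eta <- vapply(seq_len(nrow(slots)), function(i) {
    present <- slots[i, slots[i, ] != "."]
    if (length(present) == 0) return(0)
    tab <- table(present)
    e <- sum(vapply(names(tab), function(k) {
      unname(eff("beta", k) + eff("slope", k) * (tab[[k]] - 1))
    }, numeric(1)))
    if (length(tab) >= 2) {
      prs <- combn(sort(names(tab)), 2)
      e <- e + sum(vapply(seq_len(ncol(prs)), function(j) {
        unname(eff("gamma", paste(prs[, j], collapse = ";")))
      }, numeric(1)))
    }
    occ_idx <- which(slots[i, ] != ".")
    e + sum(vapply(seq_along(occ_idx), function(j) {
      unname(eff("delta", sprintf("%s@%d", slots[i, occ_idx[j]], j)))
    }, numeric(1)))
  }, numeric(1))
  names(eta) <- rownames(slots)
  if (!is.null(designs$is_control) && !is.null(effects$control)) {
    ctl <- designs$oligo_id[designs$is_control]
    if (length(ctl) > 0) eta[ctl] <- eff("control", ctl)
  }
  n <- nrow(slots)
  with_seed(seed, {
    size <- 1 / dispersion
    abundance <- rlnorm(n, 0, abundance_sdlog)
    dna_mu <- abundance / mean(abundance) * depth
    dna <- matrix(rnbinom(n * n_dna_reps, mu = dna_mu, size = size),
                  nrow = n,
                  dimnames = list(rownames(slots),
                                  sprintf("DNA%d", seq_len(n_dna_reps))))
    dna_cpm_mean <- rowMeans(cpm(dna))
    rna <- matrix(0L, nrow = n, ncol = n_rna_reps,
                  dimnames = list(rownames(slots),
                                  sprintf("RNA%d", seq_len(n_rna_reps))))
    for (r in seq_len(n_rna_reps)) {
      eta_r <- eta
      if (rep_effect_sd > 0) eta_r <- eta_r + rnorm(n, 0, rep_effect_sd)
      rate <- dna_cpm_mean * 2^eta_r
      mu <- rate / sum(rate) * depth * n
      rna[, r] <- rnbinom(n, mu = mu, size = size)
    }
    list(dna = dna, rna = rna,
         truth = list(eta = eta, effects = effects, seed = seed))
  })
}
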