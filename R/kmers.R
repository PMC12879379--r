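# Permissive k-mer motif discovery: decomposition, Hamming-distance-1
# single-linkage clustering, PPM building, known-motif filtering and
# redundancy clustering.

#' Decompose sequences into k-mer counts
#'
#' Counts every length-`k` window on the given strand across the input
#' sequences. Sequences are deduplicated by name (region identity) first so
#' a region linked to several genes is only counted once; windows containing
#' non-ACGT characters are skipped.
#'
#' @param sequences named character vector (or `DNAStringSet`) of region
#'   sequences; names identify regions.
#' @param k k-mer length (default 12, the average JASPAR motif width).
#' @param collapse_rc if `TRUE`, a k-mer and its reverse complement are
#'   counted as one (under the lexicographically smaller representative).
#'   Off by default because downstream scanning covers both strands.
#' @return data.frame with `kmer`, `count`, ordered by `kmer`.
#' @export
decompose_kmers <- function(sequences, k = 12, collapse_rc = FALSE) {
  stop_if_not(k >= 2, "k must be at least 2")
  sequences <- as.character(sequences)
  if (!is.null(names(sequences))) {
    sequences <- sequences[!duplicated(names(sequences))]
  } else {
    sequences <- unique(sequences)
  }
  sequences <- toupper(sequences)
  all_kmers <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1)
    substring(s, starts, starts + k - 1)
  }), use.names = FALSE)
  all_kmers <- all_kmers[!grepl("[^ACGT]", all_kmers)]
  if (collapse_rc) {
    rc <- revcomp(all_kmers)
    all_kmers <- ifelse(all_kmers <= rc, all_kmers, rc)
  }
  if (length(all_kmers) == 0) {
    return(data.frame(kmer = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  tab <- table(all_kmers)
  out <- data.frame(kmer = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster k-mers at Hamming distance one
#'
#' Single-linkage clustering: clusters are the connected components of the
#' graph joining k-mers at Hamming distance <= 1, so members of a cluster can
#' differ by more than one base overall as long as they are chained through
#' one-mismatch neighbours. Implemented with wildcard buckets (each k-mer
#' keyed k times with one position masked) and union-find, O(n k).
#'
#' @param kmers character vector of equal-length k-mers, or the data.frame
#'   from [decompose_kmers()].
#' @return data.frame with `kmer`, `count` (1 if none supplied) and
#'   `cluster_id` (dense integers numbered by first appearance).
#' @export
cluster_hamming <- function(kmers) {
  if (is.data.frame(kmers)) {
    counts <- kmers$count
    kmers <- kmers$kmer
  } else {
    counts <- rep(1L, length(kmers))
  }
  n <- length(kmers)
  if (n == 0) {
    return(data.frame(kmer = character(0), count = integer(0),
                      cluster_id = integer(0), stringsAsFactors = FALSE))
  }
  stop_if_not(length(unique(nchar(kmers))) == 1,
              "all k-mers must have the same length")
  stop_if_not(!anyDuplicated(kmers), "k-mers must be unique")
  k <- nchar(kmers[1])

  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <- root; i <- nxt }
    parent <<- parent
    root
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (pos in seq_len(k)) {
    masked <- paste0(substr(kmers, 1, pos - 1), ".",
                     substr(kmers, pos + 1, k))
    groups <- split(seq_len(n), masked)
    for (g in groups) {
      if (length(g) > 1) for (j in g[-1]) union(g[1], j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster_id <- match(roots, unique(roots))
  data.frame(kmer = kmers, count = counts, cluster_id = cluster_id,
             stringsAsFactors = FALSE)
}

#' Build a position probability matrix from a k-mer cluster
#'
#' Column j's probability of base b is the count-weighted frequency of b at
#' position j over the cluster members. No pseudocount is added here; that
#' happens at the log-odds ([ppm_to_pwm()]) stage.
#'
#' @param kmers character vector of cluster member k-mers.
#' @param counts occurrence counts (default 1 each).
#' @param motif_id identifier for the resulting motif.
#' @return a [ppm] with `total_weight` = sum of member counts.
#' @export
build_ppm <- function(kmers, counts = rep(1L, length(kmers)),
                      motif_id = "cluster") {
  stop_if_not(length(kmers) >= 1, "empty cluster")
  stop_if_not(length(counts) == length(kmers), "counts must match kmers")
  k <- nchar(kmers[1])
  letters <- do.call(rbind, strsplit(kmers, "", fixed = TRUE))
  m <- vapply(seq_len(k), function(j) {
    v <- vapply(DNA_BASES,
                function(b) sum(counts[letters[, j] == b]), numeric(1))
    v / sum(v)
  }, numeric(4))
  rownames(m) <- DNA_BASES
  ppm(motif_id, m, source = "novel", total_weight = sum(counts))
}

#' Discover novel motifs from regulatory-region sequences
#'
#' Full permissive pipeline: k-mer decomposition, Hamming-1 clustering, PPM
#' building, removal of PPMs matching known motifs, and redundancy
#' clustering down to representatives. Clusters are kept regardless of size
#' by default (`min_weight = 1`).
#'
#' @inheritParams decompose_kmers
#' @param known list of known [ppm]s (e.g. from [read_meme()]) used to
#'   filter out rediscovered TFBS; `NULL` skips the filter.
#' @param r_match similarity at or above which a novel PPM is considered a
#'   known-motif match (default 0.75).
#' @param r_cluster similarity threshold for redundancy clustering
#'   (default 0.9).
#' @param min_overlap minimum aligned columns for similarity scoring.
#' @param min_weight optional minimum summed k-mer count per cluster.
#' @return list with `motifs` (representative novel [ppm]s), `all_ppms`
#'   (before known-motif filtering), `matched` (novel/known match table) and
#'   `clusters` (k-mer cluster assignment).
#' @export
discover_motifs <- function(sequences, k = 12, known = NULL,
                            r_match = 0.75, r_cluster = 0.9, min_overlap = 8,
                            min_weight = 1, collapse_rc = FALSE) {
  km <- decompose_kmers(sequences, k = k, collapse_rc = collapse_rc)
  cl <- cluster_hamming(km)
  ids <- sort(unique(cl$cluster_id))
  ppms <- lapply(ids, function(i) {
    rows <- cl[cl$cluster_id == i, , drop = FALSE]
    build_ppm(rows$kmer, rows$count,
              motif_id = sprintf("KM%05d", i))
  })
  names(ppms) <- vapply(ppms, `[[`, "", "motif_id")
  weights <- vapply(ppms, `[[`, numeric(1), "total_weight")
  ppms <- ppms[weights >= min_weight]
  flt <- filter_known(ppms, known, r_match = r_match,
                      min_overlap = min_overlap)
  reps <- cluster_redundant(flt$retained, r_cluster = r_cluster,
                            min_overlap = min_overlap)
  list(motifs = reps, all_ppms = ppms, matched = flt$matched, clusters = cl)
}
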