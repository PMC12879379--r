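# Regulatory-region curation, proximal/distal classification, and linking of
# distal regions to genes through chromatin interactions. Region tables use
# BED conventions throughout: 0-based half-open [start, end) coordinates.

region_key <- function(regions) {
  sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
}

.regions_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
}

.check_regions <- function(regions) {
  stop_if_not(all(c("chrom", "start", "end") %in% names(regions)),
              "regions need chrom, start, end columns")
  stop_if_not(all(regions$start >= 0 & regions$start < regions$end),
              "regions must satisfy 0 <= start < end")
  regions
}

#' Keep regions annotated in every required sample group
#'
#' A region is retained only if the same region annotation appears in at
#' least one sample of every required group (e.g. one CD4+ and one CD8+
#' T-cell sample). Regions on excluded chromosomes (sex/mitochondrial by
#' default) are dropped. Matching is by exact region identity
#' (chrom:start-end) by default, reflecting a source annotation that calls
#' the same region across samples; `match = "overlap"` instead requires a
#' >= 1 bp overlap with a region of every required group.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and a `sample`
#'   column naming the sample each annotation came from.
#' @param sample_group named character vector mapping sample id to group.
#' @param required_groups character vector of groups that must all support a
#'   region.
#' @param exclude_chroms chromosomes to drop entirely.
#' @param match `"identity"` or `"overlap"`.
#' @return data.frame of unique supported regions with a `region_id` column.
#' @export
require_group_support <- function(regions, sample_group, required_groups,
                                  exclude_chroms = c("Y", "MT", "chrY", "chrM"),
                                  match = c("identity", "overlap")) {
  match <- match.arg(match)
  .check_regions(regions)
  stop_if_not("sample" %in% names(regions), "regions need a 'sample' column")
  stop_if_not(all(regions$sample %in% names(sample_group)),
              "every sample needs a group label")
  unknown <- setdiff(required_groups, unique(sample_group))
  if (length(unknown) > 0) {
    stop("unknown group name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  regions <- regions[!(regions$chrom %in% exclude_chroms), , drop = FALSE]
  grp <- unname(sample_group[regions$sample])

  uniq <- unique(regions[, c("chrom", "start", "end")])
  rownames(uniq) <- NULL
  if (nrow(uniq) == 0) {
    uniq$region_id <- character(0)
    return(uniq)
  }
  if (match == "identity") {
    keys <- region_key(regions)
    ukeys <- region_key(uniq)
    ok <- rep(TRUE, nrow(uniq))
    for (g in required_groups) {
      ok <- ok & (ukeys %in% keys[grp == g])
    }
  } else {
    ugr <- .regions_gr(uniq)
    ok <- rep(TRUE, nrow(uniq))
    for (g in required_groups) {
      ggr <- .regions_gr(regions[grp == g, , drop = FALSE])
      ok <- ok & IRanges::overlapsAny(ugr, ggr, minoverlap = 1L)
    }
  }
  out <- uniq[ok, , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- region_key(out)
  out
}

#' Merge regions that overlap by at least one base pair
#'
#' Overlapping regions are collapsed into their union; bookended regions
#' (one ending where the next starts) share no base under the half-open
#' convention and are not merged. Idempotent.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return data.frame of disjoint merged regions with fresh `region_id`s.
#' @export
merge_overlapping <- function(regions) {
  .check_regions(regions)
  gr <- GenomicRanges::reduce(.regions_gr(regions), min.gapwidth = 0L)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- region_key(out)
  out
}

#' Classify regions as promoter-proximal or distal
#'
#' A region is proximal if its nearest edge lies within `window` bp
#' (inclusive) of any transcription start site, or if a TSS falls inside it;
#' otherwise distal.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (and optionally
#'   `region_id`; one is added if absent).
#' @param tss data.frame with `gene_id`, `chrom`, `tss` (0-based position)
#'   and optionally `strand`.
#' @param window distance threshold in bp (default 500).
#' @return `regions` with a `region_class` column (`"proximal"`/`"distal"`).
#' @export
classify_proximal_distal <- function(regions, tss, window = 500) {
  .check_regions(regions)
  if (is.null(regions$region_id)) regions$region_id <- region_key(regions)
  known <- tss$chrom %in% unique(regions$chrom)
  if (any(!known)) {
    warning(sum(!known), " TSS on chromosomes absent from the region set ",
            "were skipped")
    tss <- tss[known, , drop = FALSE]
  }
  regions$region_class <- "distal"
  if (nrow(tss) > 0 && nrow(regions) > 0) {
    rgr <- .regions_gr(regions)
    tgr <- GenomicRanges::GRanges(tss$chrom,
                                  IRanges::IRanges(tss$tss + 1L, width = 1L))
    hit <- GenomicRanges::distanceToNearest(rgr, tgr)
    d <- S4Vectors::mcols(hit)$distance
    prox <- S4Vectors::queryHits(hit)[d <= window]
    regions$region_class[prox] <- "proximal"
  }
  rownames(regions) <- NULL
  regions
}

# Proximal region -> gene assignment: a gene owns every proximal region
# within `window` bp of its TSS.
assign_proximal <- function(regions, tss, window = 500) {
  prox <- regions[regions$region_class == "proximal", , drop = FALSE]
  if (nrow(prox) == 0 || nrow(tss) == 0) {
    return(data.frame(gene_id = character(0), region_id = character(0),
                      region_class = character(0), stringsAsFactors = FALSE))
  }
  rgr <- .regions_gr(prox)
  tgr <- GenomicRanges::GRanges(tss$chrom,
                                IRanges::IRanges(tss$tss + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(rgr, tgr, maxgap = window)
  data.frame(gene_id = tss$gene_id[S4Vectors::subjectHits(ov)],
             region_id = prox$region_id[S4Vectors::queryHits(ov)],
             region_class = "proximal", stringsAsFactors = FALSE)
}

#' Link distal regions to genes through chromatin interactions
#'
#' For each gene, finds interactions with either bin overlapping (>= 1 bp)
#' one of the gene's proximal regions, then assigns every distal region
#' overlapping either bin of such an interaction to that gene.
#'
#' @param proximal_links data.frame with `gene_id`, `region_id` pairs for
#'   proximal regions (see [assign_proximal()] or [build_gene_region_map()]).
#' @param regions classified region table ([classify_proximal_distal()]).
#' @param interactions data.frame with `chrom1`, `start1`, `end1`, `chrom2`,
#'   `start2`, `end2` and optionally `score` (BEDPE-style, 0-based
#'   half-open bins).
#' @param min_score optional lower bound; interactions with `score` not
#'   exceeding it are ignored.
#' @return data.frame with `gene_id`, `region_id`, `region_class = "distal"`.
#' @export
link_distal_regions <- function(proximal_links, regions, interactions,
                                min_score = NULL) {
  distal <- regions[regions$region_class == "distal", , drop = FALSE]
  empty <- data.frame(gene_id = character(0), region_id = character(0),
                      region_class = character(0), stringsAsFactors = FALSE)
  if (nrow(distal) == 0 || nrow(interactions) == 0 ||
      nrow(proximal_links) == 0) {
    return(empty)
  }
  if (!is.null(min_score) && !is.null(interactions$score)) {
    interactions <- interactions[interactions$score > min_score, , drop = FALSE]
    if (nrow(interactions) == 0) return(empty)
  }
  bins1 <- data.frame(chrom = interactions$chrom1, start = interactions$start1,
                      end = interactions$end1)
  bins2 <- data.frame(chrom = interactions$chrom2, start = interactions$start2,
                      end = interactions$end2)
  b1 <- .regions_gr(.check_regions(bins1))
  b2 <- .regions_gr(.check_regions(bins2))

  prox <- regions[base::match(unique(proximal_links$region_id),
                              regions$region_id), , drop = FALSE]
  pgr <- .regions_gr(prox)
  dgr <- .regions_gr(distal)

  # interaction x proximal-region overlap (either bin)
  ov_p <- rbind(
    as.data.frame(GenomicRanges::findOverlaps(b1, pgr, minoverlap = 1L)),
    as.data.frame(GenomicRanges::findOverlaps(b2, pgr, minoverlap = 1L)))
  if (nrow(ov_p) == 0) return(empty)
  # interaction x distal-region overlap (either bin)
  ov_d <- rbind(
    as.data.frame(GenomicRanges::findOverlaps(b1, dgr, minoverlap = 1L)),
    as.data.frame(GenomicRanges::findOverlaps(b2, dgr, minoverlap = 1L)))
  if (nrow(ov_d) == 0) return(empty)

  # gene -> interaction (via proximal region), interaction -> distal region
  gene_by_region <- split(proximal_links$gene_id, proximal_links$region_id)
  genes_per_int <- split(
    unlist(gene_by_region[prox$region_id[ov_p$subjectHits]], use.names = FALSE),
    rep(ov_p$queryHits,
        lengths(gene_by_region[prox$region_id[ov_p$subjectHits]])))
  distal_per_int <- split(distal$region_id[ov_d$subjectHits], ov_d$queryHits)

  shared <- intersect(names(genes_per_int), names(distal_per_int))
  if (length(shared) == 0) return(empty)
  links <- do.call(rbind, lapply(shared, function(i) {
    expand.grid(gene_id = unique(genes_per_int[[i]]),
                region_id = unique(distal_per_int[[i]]),
                stringsAsFactors = FALSE)
  }))
  links <- unique(links)
  links <- links[order(links$gene_id, links$region_id), , drop = FALSE]
  rownames(links) <- NULL
  links$region_class <- "distal"
  links
}

#' Build a gene-to-regulatory-region map
#'
#' Classifies regions as proximal or distal against the TSS table, assigns
#' proximal regions to genes within `window` bp, and links distal regions
#' through the interaction table.
#'
#' @inheritParams classify_proximal_distal
#' @inheritParams link_distal_regions
#' @return object of class `gene_region_map`: a list with `links`
#'   (`gene_id`, `region_id`, `region_class`), the classified `regions`, and
#'   the `tss` table.
#' @export
build_gene_region_map <- function(regions, tss, interactions = NULL,
                                  window = 500, min_score = NULL) {
  regions <- classify_proximal_distal(regions, tss, window = window)
  prox <- assign_proximal(regions, tss, window = window)
  dist <- if (is.null(interactions)) {
    prox[0, , drop = FALSE]
  } else {
    link_distal_regions(prox, regions, interactions, min_score = min_score)
  }
  links <- rbind(prox, dist)
  rownames(links) <- NULL
  structure(list(links = links, regions = regions, tss = tss),
            class = "gene_region_map")
}

#' @export
print.gene_region_map <- function(x, ...) {
  cat(sprintf(
    "gene_region_map: %d genes, %d regions (%d proximal, %d distal links)\n",
    length(unique(x$tss$gene_id)), nrow(x$regions),
    sum(x$links$region_class == "proximal"),
    sum(x$links$region_class == "distal")))
  invisible(x)
}
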