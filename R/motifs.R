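#' Position probability matrix
#'
#' A PPM stores per-position letter probabilities for a DNA motif as a
#' 4 x L matrix with rows `A`, `C`, `G`, `T`. Every column must sum to 1.
#'
#' @param motif_id character scalar identifier.
#' @param matrix numeric 4 x L matrix of probabilities; rows are taken in
#'   A, C, G, T order (rownames, if present, are checked).
#' @param source `"novel"` or `"known"`.
#' @param total_weight summed occurrence count of the k-mers the PPM was
#'   built from (`NA` for imported motifs).
#' @return an object of class `ppm`.
#' @examples
#' m <- matrix(c(1, 0, 0, 0, 0.25, 0.25, 0.25, 0.25), nrow = 4)
#' ppm("toy", m)
#' @export
ppm <- function(motif_id, matrix, source = c("novel", "known"),
                total_weight = NA_real_) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  stop_if_not(nrow(matrix) == 4, "a PPM matrix must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(matrix))) {
    stop_if_not(identical(toupper(rownames(matrix)), DNA_BASES),
                "PPM rownames must be A, C, G, T")
  }
  rownames(matrix) <- DNA_BASES
  stop_if_not(all(matrix >= -1e-12), "PPM probabilities must be non-negative")
  stop_if_not(all(abs(colSums(matrix) - 1) <= 1e-9),
              "every PPM column must sum to 1")
  structure(
    list(motif_id = as.character(motif_id), matrix = matrix,
         source = source, total_weight = as.numeric(total_weight)),
    class = "ppm")
}

#' @export
print.ppm <- function(x, ...) {
  cat(sprintf("PPM %s (%s): %d columns, consensus %s\n",
              x$motif_id, x$source, ncol(x$matrix), consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PPM
#'
#' The most probable letter at each position (ties broken in A,C,G,T order).
#'
#' @param x a [ppm] object.
#' @return character scalar.
#' @export
consensus <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Reverse complement of a PPM
#'
#' @param x a [ppm] object.
#' @return a [ppm] with columns reversed and letters complemented.
#' @export
rc_ppm <- function(x) {
  m <- x$matrix[4:1, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  rownames(m) <- DNA_BASES
  ppm(x$motif_id, m, source = x$source, total_weight = x$total_weight)
}

#' Read motifs from MEME minimal format
#'
#' Parses the minimal motif format (as produced by JASPAR exports and by
#' [write_meme()]): a `MEME version` header, optional alphabet/background
#' lines, and `MOTIF` blocks each followed by a
#' `letter-probability matrix:` section.
#'
#' @param path file path.
#' @param source motif source label attached to each parsed [ppm].
#' @return named list of [ppm] objects.
#' @export
read_meme <- function(path, source = "known") {
  lines <- readLines(path)
  idx <- grep("^MOTIF\\b", lines)
  stop_if_not(length(idx) > 0, sprintf("no MOTIF blocks found in %s", path))
  out <- list()
  for (i in seq_along(idx)) {
    header <- strsplit(trimws(lines[idx[i]]), "\\s+")[[1]]
    id <- header[2]
    block_end <- if (i < length(idx)) idx[i + 1] - 1 else length(lines)
    block <- lines[idx[i]:block_end]
    mat_at <- grep("^letter-probability matrix", block)
    stop_if_not(length(mat_at) == 1,
                sprintf("motif %s: missing letter-probability matrix", id))
    w <- sub(".*w=\\s*(\\d+).*", "\\1", block[mat_at])
    w <- suppressWarnings(as.integer(w))
    rows <- block[-seq_len(mat_at)]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    if (!is.na(w)) rows <- utils::head(rows, w)
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    m <- t(do.call(rbind, vals))
    # rows may not sum to exactly 1 in published files; renormalise
    m <- sweep(m, 2, colSums(m), "/")
    out[[id]] <- ppm(id, m, source = source)
  }
  out
}

#' Write motifs in MEME minimal format
#'
#' @param ppms a [ppm] or list of them.
#' @param path output file path.
#' @param background length-4 background letter frequencies (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme <- function(ppms, path, background = rep(0.25, 4)) {
  if (is(ppms, "ppm")) ppms <- list(ppms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
               ""), con)
  for (p in ppms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(p$matrix),
                       max(1L, as.integer(round(p$total_weight)), na.rm = TRUE)),
               con)
    writeLines(apply(p$matrix, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
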