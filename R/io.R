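# Readers and writers for the toolkit's tabular and sequence formats.
# Region coordinates follow BED conventions (0-based half-open) on disk
# and in memory.

#' Read a gene expression matrix from TSV
#'
#' First column gene ids, remaining columns samples.
#'
#' @param path TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a sample-to-group map from TSV
#'
#' Needs `sample_id` and `group` columns (extra columns such as
#' `cell_type` are ignored).
#'
#' @param path TSV file.
#' @return named character vector: sample id -> group.
#' @export
read_sample_groups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("sample_id", "group") %in% names(df)),
              "sample map needs sample_id and group columns")
  setNames(df$group, df$sample_id)
}

#' Read regions from a BED3+ file
#'
#' @param path BED file (no header): chrom, start, end, then optional
#'   columns.
#' @param sample optional sample id attached as a `sample` column.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `region_id`.
#' @export
read_bed <- function(path, sample = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                    stringsAsFactors = FALSE)
  .check_regions(out)
  out$region_id <- region_key(out)
  if (!is.null(sample)) out$sample <- sample
  out
}

#' Read chromatin interactions from a BEDPE file
#'
#' @param path BEDPE file (no header): chrom1 start1 end1 chrom2 start2
#'   end2 [name score].
#' @return data.frame with the standard BEDPE columns.
#' @export
read_bedpe <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom1 = as.character(df[[1]]),
                    start1 = as.integer(df[[2]]),
                    end1 = as.integer(df[[3]]),
                    chrom2 = as.character(df[[4]]),
                    start2 = as.integer(df[[5]]),
                    end2 = as.integer(df[[6]]),
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 7) out$name <- as.character(df[[7]])
  if (ncol(df) >= 8) out$score <- as.numeric(df[[8]])
  out
}

#' Read a TSS table from TSV
#'
#' Needs `gene_id`, `chrom`, `tss` columns (`strand` optional); `tss` is a
#' 0-based position.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_tss <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("gene_id", "chrom", "tss") %in% names(df)),
              "TSS table needs gene_id, chrom, tss columns")
  df
}

#' Read a count matrix from TSV
#'
#' First column oligo (or feature) ids, remaining columns replicates.
#'
#' @param path TSV file.
#' @return integer matrix.
#' @export
read_counts <- function(path) {
  m <- read_expression_matrix(path)
  storage.mode(m) <- "integer"
  m
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
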