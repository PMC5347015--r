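#' Construct a unique-read count matrix
#'
#' The central container for per-gene unique-read counts of named samples.
#' `library_sizes` holds the per-sample total of uniquely mapped reads used
#' as the normalisation denominator (RPKM) and as the library totals N1/N2
#' of the exact two-library test.  When not supplied it defaults to the
#' column sums, i.e. every uniquely mapped read is assumed to hit a counted
#' gene.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative integers.
#' @param library_sizes optional named numeric vector, one positive total
#'   per sample; must be >= the corresponding column sum.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `library_sizes` (named numeric).
#' @examples
#' m <- matrix(c(10L, 20L, 30L, 40L), 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' count_matrix(m)
#' @export
count_matrix <- function(counts, library_sizes = NULL) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("'counts' must be a matrix with gene rownames and sample colnames")
  if (nrow(counts) == 0L) stopf("count matrix has no genes")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate gene id: %s",
          rownames(counts)[anyDuplicated(rownames(counts))])
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample id")
  if (!is_count(counts)) stopf("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  cs <- colSums(counts)
  if (is.null(library_sizes)) {
    library_sizes <- cs
  } else {
    if (is.null(names(library_sizes))) names(library_sizes) <- colnames(counts)
    library_sizes <- library_sizes[colnames(counts)]
    if (anyNA(library_sizes) || any(library_sizes <= 0))
      stopf("library_sizes must be positive and cover every sample")
    if (any(library_sizes < cs))
      stopf("library size smaller than column sum for sample '%s'",
            colnames(counts)[which(library_sizes < cs)[1L]])
  }
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:",
      paste(sprintf("%s=%s", names(x$library_sizes),
                    format(x$library_sizes, big.mark = ",")), collapse = ", "),
      "\n")
  print(head(x$counts, 5L))
  if (nrow(x$counts) > 5L) cat("...\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count table from TSV
#'
#' Expects a header row `gene_id<TAB>sample...`, one gene per row.  An
#' optional comment line `#library_size <s1> <s2> ...` (anywhere before the
#' data, whitespace- or tab-separated) declares per-sample totals of
#' uniquely mapped reads; without it the column sums are used.
#'
#' @param path path to a TSV file.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  size_line <- grep("^#library_size\\b", lines, value = TRUE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stopf("empty count table: %s", path)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stopf("count table needs gene_id plus >=1 sample column")
  gene_id <- df[[1L]]
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) stopf("duplicate gene_id '%s' in %s", dup[1L], path)
  samples <- colnames(df)[-1L]
  cells <- as.matrix(df[-1L])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-integer or negative count at row %d, column '%s'",
          bad[1L, 1L], samples[bad[1L, 2L]])
  dimnames(num) <- list(gene_id, samples)
  sizes <- NULL
  if (length(size_line)) {
    toks <- strsplit(trimws(size_line[1L]), "[ \t]+")[[1L]][-1L]
    sizes <- as.numeric(toks)
    if (anyNA(sizes) || length(sizes) != length(samples))
      stopf("#library_size line must give one number per sample")
    names(sizes) <- samples
  }
  count_matrix(num, sizes)
}

#' Write a count table to TSV
#'
#' Emits the `#library_size` comment line followed by the counts, so that
#' [read_count_table()] round-trips counts, sample order and library sizes
#' exactly.
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#library_size",
                     format(x$library_sizes, scientific = FALSE, trim = TRUE)),
                   collapse = "\t"), con)
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene lengths from a two-column TSV
#'
#' @param path TSV with columns gene_id and length in base pairs (a header
#'   row is detected and skipped if the second field is not numeric).
#' @return Named integer vector of gene lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 2L) stopf("gene length file must have exactly 2 columns")
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[[2L]][1L]))))
    df <- df[-1L, , drop = FALSE]
  if (!nrow(df)) stopf("empty gene length file: %s", path)
  len <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(len) || any(len != floor(len)))
    stopf("non-integer gene length at line %d",
          which(is.na(len) | len != floor(len))[1L])
  if (any(len <= 0))
    stopf("gene '%s' has non-positive length", df[[1L]][which(len <= 0)[1L]])
  if (anyDuplicated(df[[1L]]))
    stopf("duplicate gene id '%s'", df[[1L]][duplicated(df[[1L]])][1L])
  stats::setNames(as.integer(len), df[[1L]])
}

#' Construct per-sample read-mapping statistics
#'
#' Holds the alignment tallies reported for one sequencing library, with the
#' three bookkeeping identities enforced: mapped + unmapped = total reads;
#' perfect + (<=2 bp mismatch) = mapped; unique + multi-position = mapped.
#'
#' @param total_reads,total_base_pairs,total_mapped,perfect_match,le2_mismatch,unique_match,multi_match,unmapped
#'   non-negative integer tallies.
#' @return An object of class `sample_stats` (named list of the tallies).
#' @export
sample_stats <- function(total_reads, total_base_pairs, total_mapped,
                         perfect_match, le2_mismatch, unique_match,
                         multi_match, unmapped) {
  v <- c(total_reads = total_reads, total_base_pairs = total_base_pairs,
         total_mapped = total_mapped, perfect_match = perfect_match,
         le2_mismatch = le2_mismatch, unique_match = unique_match,
         multi_match = multi_match, unmapped = unmapped)
  if (!is_count(v)) stopf("all tallies must be non-negative integers")
  if (total_mapped + unmapped != total_reads)
    stopf("mapped + unmapped != total reads")
  if (perfect_match + le2_mismatch != total_mapped)
    stopf("perfect + <=2bp-mismatch != mapped")
  if (unique_match + multi_match != total_mapped)
    stopf("unique + multi-position != mapped")
  structure(as.list(v), class = "sample_stats")
}
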