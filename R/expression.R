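#' RPKM: reads per kilobase of gene model per million uniquely mapped reads
#'
#' `rpkm = 1e9 * count / (length_bp * total_unique)`.  The denominator is
#' the per-sample total of uniquely mapped reads, so the value is linear in
#' the count and inversely linear in gene length and library size.
#'
#' @param count non-negative integer read count(s), uniquely mapped to the
#'   gene.
#' @param length_bp gene model length in base pairs (>= 1).
#' @param total_unique total uniquely mapped reads in the sample (>= 1).
#' @return Numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10 reads on a 1 kb gene in a 1 M-read library -> 10
#' @export
rpkm <- function(count, length_bp, total_unique) {
  if (any(total_unique < 1)) stopf("total_unique must be >= 1")
  if (any(length_bp < 1)) stopf("length_bp must be >= 1")
  if (any(count < 0)) stopf("counts must be non-negative")
  1e9 * count / (length_bp * total_unique)
}

#' RPKM matrix from a count matrix and gene lengths
#'
#' @param counts a [count_matrix()]; the per-sample denominators are its
#'   `library_sizes`.
#' @param lengths named integer vector of gene lengths in bp covering every
#'   counted gene (see [read_gene_lengths()]).
#' @return Numeric matrix of RPKM values with the same dimnames as the
#'   counts.
#' @export
rpkm_matrix <- function(counts, lengths) {
  stopifnot(inherits(counts, "count_matrix"))
  genes <- rownames(counts$counts)
  missing <- setdiff(genes, names(lengths))
  if (length(missing))
    stopf("no gene length for: %s%s",
          paste(head(missing, 5L), collapse = ", "),
          if (length(missing) > 5L) sprintf(" (and %d more)",
                                            length(missing) - 5L) else "")
  len <- as.numeric(lengths[genes])
  sz <- counts$library_sizes[colnames(counts$counts)]
  1e9 * sweep(counts$counts / len, 2L, sz, "/")
}

#' Write an RPKM matrix as TSV
#'
#' @param x numeric matrix from [rpkm_matrix()].
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  write_tsv(data.frame(gene_id = rownames(x), x, check.names = FALSE), path)
}

#' Mapping-statistics summary with rendered percentages
#'
#' Expresses each alignment tally of a library as a proportion of its total
#' reads, rendered as a two-decimal percentage (half away from zero), the
#' conventional layout of RNA-seq mapping reports.  `total_base_pairs` is
#' carried through but not expressed as a rate (it is not a read count).
#'
#' @param stats a [sample_stats()] object.
#' @return Data frame with columns `field`, `reads`, `proportion`,
#'   `percent` (rendered string).
#' @export
mapping_summary <- function(stats) {
  stopifnot(inherits(stats, "sample_stats"))
  if (stats$total_reads == 0) stopf("total_reads is zero")
  fields <- c("total_reads", "total_mapped", "perfect_match", "le2_mismatch",
              "unique_match", "multi_match", "unmapped")
  reads <- unlist(stats[fields])
  prop <- reads / stats$total_reads
  data.frame(field = fields, reads = as.numeric(reads), proportion = prop,
             percent = format_percent(prop), row.names = NULL)
}
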