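#' Clean-read filtering parameters
#'
#' Defaults follow the common clean-read definition for HiSeq-era libraries:
#' drop a read if it contains an adapter, if more than 10% of its bases are
#' N, or if more than 50% of its bases have Phred quality <= 5.  Both
#' fraction thresholds are strict ("greater than"), so a read sitting
#' exactly at 10% N or 50% low-quality bases is kept.
#'
#' @param adapters character vector of adapter sequences (exact substring
#'   match; empty vector disables the adapter rule).
#' @param max_n_fraction maximum tolerated fraction of N bases (strict).
#' @param low_quality_phred Phred score at or below which a base counts as
#'   low quality.
#' @param max_low_quality_fraction maximum tolerated fraction of low-quality
#'   bases (strict).
#' @param phred_offset quality encoding offset, 33 (Sanger/Illumina 1.8+) or
#'   64 (Illumina 1.3-1.7).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(adapters = character(), max_n_fraction = 0.10,
                      low_quality_phred = 5L, max_low_quality_fraction = 0.50,
                      phred_offset = 33L) {
  if (max_n_fraction < 0 || max_n_fraction > 1 ||
      max_low_quality_fraction < 0 || max_low_quality_fraction > 1)
    stopf("fraction thresholds must lie in [0, 1]")
  if (!phred_offset %in% c(33L, 64L)) stopf("phred_offset must be 33 or 64")
  structure(list(adapters = as.character(adapters),
                 max_n_fraction = max_n_fraction,
                 low_quality_phred = as.integer(low_quality_phred),
                 max_low_quality_fraction = max_low_quality_fraction,
                 phred_offset = as.integer(phred_offset)),
            class = "qc_params")
}

#' Fraction of unknown (N) bases in a read
#'
#' @param sequence character vector of nucleotide strings.
#' @return Numeric vector in `[0, 1]`: the per-read proportion of `N`
#'   (case-insensitive).
#' @examples
#' fraction_n("ACGTNNNNNN")  # 0.6
#' @export
fraction_n <- function(sequence) {
  n <- nchar(sequence)
  if (any(n == 0L)) stopf("empty sequence")
  nn <- nchar(gsub("[^Nn]", "", sequence))
  nn / n
}

#' Fraction of low-quality bases in a read
#'
#' Decodes a Phred-encoded quality string and returns the proportion of
#' bases whose score is `<= low_quality_phred`.
#'
#' @param quality character vector of quality strings.
#' @param phred_offset 33 or 64.
#' @param low_quality_phred score threshold (inclusive).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' fraction_low_quality("&&&&&IIIII")  # five Q5 bases out of ten -> 0.5
#' @export
fraction_low_quality <- function(quality, phred_offset = 33L,
                                 low_quality_phred = 5L) {
  if (any(nchar(quality) == 0L)) stopf("empty quality string")
  vapply(quality, function(q) {
    sc <- utf8ToInt(q) - phred_offset
    if (any(sc < 0))
      stopf("quality character decodes below 0 with offset %d", phred_offset)
    mean(sc <= low_quality_phred)
  }, 0, USE.NAMES = FALSE)
}

#' Does a read contain an adapter sequence?
#'
#' Exact contiguous substring match against each supplied adapter.
#'
#' @param sequence character vector of reads.
#' @param adapters character vector of adapter sequences; an empty vector
#'   matches nothing.
#' @return Logical vector.
#' @export
contains_adapter <- function(sequence, adapters) {
  hit <- rep(FALSE, length(sequence))
  for (ad in adapters) {
    if (!nzchar(ad)) stopf("adapters must be non-empty strings")
    hit <- hit | grepl(ad, sequence, fixed = TRUE)
  }
  hit
}

#' Read / write FASTQ
#'
#' Thin wrappers over Biostrings keeping reads as a plain data frame of
#' `read_id`, `sequence`, `quality` so the filtering rules can work on
#' character vectors.
#'
#' @param path FASTQ file (optionally gzip-compressed on input).
#' @return `read_fastq()`: a data frame with columns `read_id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

#' @param reads a data frame as returned by [read_fastq()].
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$quality))
  writeLines(lines, path)
  invisible(path)
}

qc_report <- function(n_input, n_kept, n_dropped_adapter,
                      n_dropped_n_fraction, n_dropped_low_quality) {
  r <- list(n_input = n_input, n_kept = n_kept,
            n_dropped_adapter = n_dropped_adapter,
            n_dropped_n_fraction = n_dropped_n_fraction,
            n_dropped_low_quality = n_dropped_low_quality)
  stopifnot(n_input == n_kept + n_dropped_adapter + n_dropped_n_fraction +
              n_dropped_low_quality)
  structure(r, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "clean-read filter: %d in, %d kept (%s); dropped %d adapter, %d N-heavy, %d low-quality\n",
    x$n_input, x$n_kept,
    if (x$n_input) format_percent(x$n_kept / x$n_input) else "-",
    x$n_dropped_adapter, x$n_dropped_n_fraction, x$n_dropped_low_quality))
  invisible(x)
}

#' @method as.data.frame qc_report
#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(category = c("input", "kept", "dropped_adapter",
                          "dropped_n_fraction", "dropped_low_quality"),
             reads = c(x$n_input, x$n_kept, x$n_dropped_adapter,
                       x$n_dropped_n_fraction, x$n_dropped_low_quality))
}

#' Filter a FASTQ read set down to clean reads
#'
#' Applies the three clean-read rules in fixed precedence: a read is dropped
#' as *adapter* if any adapter occurs in it; otherwise as *N-heavy* if its N
#' fraction strictly exceeds `max_n_fraction`; otherwise as *low-quality* if
#' its fraction of bases with Phred `<= low_quality_phred` strictly exceeds
#' `max_low_quality_fraction`.  Each read lands in exactly one report
#' category and kept reads preserve input order, so filtering is idempotent.
#'
#' @param reads a data frame from [read_fastq()] (or a FASTQ path).
#' @param params a [qc_params()] object.
#' @return A list with `kept` (data frame of surviving reads) and `report`
#'   (a `qc_report`).
#' @export
filter_fastq <- function(reads, params = qc_params()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(inherits(params, "qc_params"),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stopf("malformed FASTQ record %d: sequence/quality length mismatch",
          which(nchar(reads$sequence) != nchar(reads$quality))[1L])
  n <- nrow(reads)
  if (n == 0L)
    return(list(kept = reads, report = qc_report(0L, 0L, 0L, 0L, 0L)))
  ad <- contains_adapter(reads$sequence, params$adapters)
  nf <- !ad & fraction_n(reads$sequence) > params$max_n_fraction
  lq <- !ad & !nf &
    fraction_low_quality(reads$quality, params$phred_offset,
                         params$low_quality_phred) >
      params$max_low_quality_fraction
  keep <- !(ad | nf | lq)
  list(kept = reads[keep, , drop = FALSE],
       report = qc_report(n, sum(keep), sum(ad), sum(nf), sum(lq)))
}
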