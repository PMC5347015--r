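#' Run one pairwise differential-expression contrast
#'
#' Fits the exact two-library test to every gene observed in at least one of
#' the two samples (genes with zero counts in both are excluded), adjusts
#' the p-values by Benjamini-Hochberg across the tested genes of this
#' contrast, computes the normalised log2 ratio (second sample over first),
#' and calls DEGs by the joint FDR / fold-change rule of `thresholds`.
#'
#' The library totals N1/N2 default to the `library_sizes` of the count
#' matrix, i.e. the totals of uniquely mapped reads; pass `totals` to use a
#' different pair (for example total clean reads).
#'
#' @param counts a [count_matrix()].
#' @param sample_a,sample_b sample ids; the ratio is oriented
#'   `sample_b` over `sample_a` and the contrast is named `"<a>_vs_<b>"`.
#' @param thresholds a [deg_thresholds()] object.
#' @param totals optional numeric length-2 override for (N1, N2).
#' @return An object of class `ac_contrast` with elements `contrast`,
#'   `sample_a`, `sample_b`, `n1`, `n2`, `thresholds`, `n_excluded` and
#'   `table` (data frame: gene_id, x, y, log2_ratio, p, fdr, direction,
#'   is_deg).
#' @export
run_contrast <- function(counts, sample_a, sample_b,
                         thresholds = deg_thresholds(), totals = NULL) {
  stopifnot(inherits(counts, "count_matrix"),
            inherits(thresholds, "deg_thresholds"))
  samples <- colnames(counts$counts)
  for (s in c(sample_a, sample_b))
    if (!s %in% samples) stopf("unknown sample '%s'", s)
  x <- counts$counts[, sample_a]
  y <- counts$counts[, sample_b]
  if (is.null(totals)) {
    n1 <- unname(counts$library_sizes[[sample_a]])
    n2 <- unname(counts$library_sizes[[sample_b]])
  } else {
    stopifnot(length(totals) == 2L, all(totals > 0))
    n1 <- totals[1L]; n2 <- totals[2L]
  }
  tested <- !(x == 0L & y == 0L)
  xs <- x[tested]; ys <- y[tested]
  # the p-value depends only on (x, y) given fixed totals: compute once per
  # distinct pair
  key <- paste(xs, ys)
  uniq <- !duplicated(key)
  p_uniq <- ac_two_sided_p(xs[uniq], ys[uniq], n1, n2)
  p <- p_uniq[match(key, key[uniq])]
  fdr <- bh_fdr(p)
  lr <- log2_ratio(xs, ys, n1, n2)
  is_deg <- fdr <= thresholds$max_fdr &
    abs(lr) >= thresholds$min_abs_log2_ratio
  direction <- ifelse(lr > 0, "up", ifelse(lr < 0, "down", "flat"))
  tab <- data.frame(gene_id = rownames(counts$counts)[tested],
                    x = xs, y = ys, log2_ratio = lr, p = p, fdr = fdr,
                    direction = direction, is_deg = is_deg,
                    row.names = NULL)
  structure(list(contrast = paste0(sample_a, "_vs_", sample_b),
                 sample_a = sample_a, sample_b = sample_b,
                 n1 = n1, n2 = n2, thresholds = thresholds,
                 n_excluded = sum(!tested), table = tab),
            class = "ac_contrast")
}

#' DEG gene ids of a contrast
#'
#' @param x an `ac_contrast`.
#' @return Character vector of gene ids called differentially expressed.
#' @export
deg_ids <- function(x) {
  stopifnot(inherits(x, "ac_contrast"))
  x$table$gene_id[x$table$is_deg]
}

#' @export
print.ac_contrast <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Exact two-library contrast %s (N1 = %s, N2 = %s)\n",
              x$contrast, format(x$n1, big.mark = ","),
              format(x$n2, big.mark = ",")))
  cat(sprintf("  %d genes tested, %d excluded (zero in both libraries)\n",
              nrow(x$table), x$n_excluded))
  cat(sprintf("  DEGs at FDR <= %g, |log2 ratio| >= %g: %d (%d up, %d down)\n",
              x$thresholds$max_fdr, x$thresholds$min_abs_log2_ratio,
              s$total, s$up, s$down))
  invisible(x)
}

#' @method summary ac_contrast
#' @export
summary.ac_contrast <- function(object, ...) {
  deg <- object$table[object$table$is_deg, ]
  structure(list(contrast = object$contrast, n_tested = nrow(object$table),
                 n_excluded = object$n_excluded,
                 total = nrow(deg), up = sum(deg$direction == "up"),
                 down = sum(deg$direction == "down")),
            class = "summary.ac_contrast")
}

#' @export
print.summary.ac_contrast <- function(x, ...) {
  cat(sprintf("%s: %d DEGs (%d up, %d down) of %d tested\n",
              x$contrast, x$total, x$up, x$down, x$n_tested))
  invisible(x)
}

#' Write a contrast table as TSV
#'
#' @param x an `ac_contrast`.
#' @param path output path.
#' @export
write_contrast <- function(x, path) {
  stopifnot(inherits(x, "ac_contrast"))
  tab <- x$table
  out <- data.frame(gene_id = tab$gene_id, x = tab$x, y = tab$y,
                    N1 = x$n1, N2 = x$n2, log2_ratio = tab$log2_ratio,
                    p = tab$p, fdr = tab$fdr, direction = tab$direction,
                    is_deg = tab$is_deg)
  write_tsv(out, path)
}

#' DEGs shared between two contrasts
#'
#' Both contrasts are expected to be computed against the same reference
#' sample (e.g. fast-vs-control and slow-vs-control), in which case the
#' intersection is the set of genes responsive under both treatments.
#'
#' @param a,b `ac_contrast` objects.
#' @return Character vector of gene ids.
#' @export
shared_degs <- function(a, b) {
  intersect(deg_ids(a), deg_ids(b))
}

#' Shared DEGs regulated in opposite directions
#'
#' Genes called DEG in both contrasts but up-regulated in one and
#' down-regulated in the other — the signature of rate-specific rather than
#' generic cold response when the two contrasts share a control reference.
#'
#' @param a,b `ac_contrast` objects against the same reference.
#' @return Data frame with columns `gene_id`, `dir_a`, `dir_b`.
#' @export
opposite_direction <- function(a, b) {
  ids <- shared_degs(a, b)
  da <- a$table$direction[match(ids, a$table$gene_id)]
  db <- b$table$direction[match(ids, b$table$gene_id)]
  opp <- da != db
  data.frame(gene_id = ids[opp], dir_a = da[opp], dir_b = db[opp],
             row.names = NULL)
}

#' DEG bookkeeping across three contrasts
#'
#' Per-contrast totals split by direction (up + down = total by
#' construction) plus pairwise DEG-set intersection sizes — the numbers a
#' three-set Venn diagram of DEGs displays.
#'
#' @param ... three (or more) `ac_contrast` objects, optionally named;
#'   unnamed arguments are labelled by their contrast name.
#' @return An object of class `deg_venn`: list with `per_contrast` and
#'   `intersections` data frames.
#' @export
venn_counts <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) &&
      !inherits(tabs[[1L]], "ac_contrast")) tabs <- tabs[[1L]]
  stopifnot(all(vapply(tabs, inherits, TRUE, "ac_contrast")))
  nms <- names(tabs)
  if (is.null(nms)) nms <- rep("", length(tabs))
  blank <- !nzchar(nms)
  nms[blank] <- vapply(tabs[blank], `[[`, "", "contrast")
  names(tabs) <- nms
  per <- do.call(rbind, lapply(nms, function(nm) {
    s <- summary(tabs[[nm]])
    data.frame(contrast = nm, total = s$total, up = s$up, down = s$down)
  }))
  pairs <- utils::combn(nms, 2L, simplify = FALSE)
  inter <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(contrast_a = pr[1L], contrast_b = pr[2L],
               shared = length(shared_degs(tabs[[pr[1L]]], tabs[[pr[2L]]])))
  }))
  structure(list(per_contrast = per, intersections = inter),
            class = "deg_venn")
}

#' @export
print.deg_venn <- function(x, ...) {
  cat("DEG counts per contrast:\n")
  print(x$per_contrast, row.names = FALSE)
  cat("pairwise shared DEGs:\n")
  print(x$intersections, row.names = FALSE)
  invisible(x)
}
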