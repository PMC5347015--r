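#' Upper-tail hypergeometric probability for over-representation
#'
#' `P(X >= m)` for `X ~ Hypergeometric(N, M, n)`: drawing the `n`
#' annotatable DEGs from an annotated universe of `N` genes of which `M`
#' belong to the pathway, the probability of seeing `m` or more pathway
#' members among them.  The observed `m` is included in the tail, the
#' standard over-representation convention.
#'
#' @param m DEGs in the pathway.
#' @param n annotatable DEGs.
#' @param M annotated genes in the pathway.
#' @param N all genes with pathway annotation.
#' @return Upper-tail probability; vectorised.
#' @examples
#' hypergeom_upper_p(3, 5, 4, 10)  # 66/252
#' @export
hypergeom_upper_p <- function(m, n, M, N) {
  k <- max(length(m), length(n), length(M), length(N))
  m <- rep_len(m, k); n <- rep_len(n, k)
  M <- rep_len(M, k); N <- rep_len(N, k)
  if (any(m < 0 | n < 0 | M < 0 | N < 0)) stopf("counts must be non-negative")
  if (any(m > pmin(n, M))) stopf("m must not exceed min(n, M)")
  if (any(n > N) || any(M > N)) stopf("n and M must not exceed N")
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Significance parameters for pathway enrichment
#'
#' @param alpha significance level in (0, 1).
#' @param correction multiple-testing correction across pathways,
#'   `"bonferroni"` (default) or `"none"`.
#' @return An object of class `enrichment_params`.
#' @export
enrichment_params <- function(alpha = 0.05,
                              correction = c("bonferroni", "none")) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  structure(list(alpha = alpha, correction = match.arg(correction)),
            class = "enrichment_params")
}

#' Bonferroni-adjusted p-values
#'
#' `p_adj = min(1, p * k)` with `k` the number of tests.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted values.
#' @export
bonferroni_adjust <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "bonferroni")
}

#' Pathway over-representation analysis of a DEG set
#'
#' For each pathway with at least one annotated member in the background,
#' tests whether the DEG set contains more pathway members than expected by
#' chance, via the upper-tail hypergeometric probability.  The background
#' defaults to all genes with at least one pathway annotation; DEG ids are
#' intersected with it, and `n` is the size of that intersection.
#'
#' @param deg_ids character vector of DEG gene ids.
#' @param db a [pathway_db()].
#' @param background annotation universe (defaults to
#'   [pathway_universe()] of `db`); member sets are restricted to it.
#' @param params an [enrichment_params()] object.
#' @return An object of class `pathway_enrichment`: a data frame sorted by
#'   raw p ascending with columns `pathway_id`, `name`, `m`, `n`, `M`, `N`,
#'   `percent` (100 m / n), `percent_label`, `p_raw`, `p_adj`, and
#'   attributes `n_deg` and `params`.
#' @export
enrich <- function(deg_ids, db, background = NULL,
                   params = enrichment_params()) {
  stopifnot(inherits(db, "pathway_db"), inherits(params, "enrichment_params"))
  if (is.null(background)) background <- pathway_universe(db)
  background <- unique(as.character(background))
  N <- length(background)
  deg <- intersect(unique(as.character(deg_ids)), background)
  n <- length(deg)
  if (n == 0L) stopf("no annotatable DEGs in the background universe")
  members <- lapply(db$members, intersect, background)
  keep <- lengths(members) >= 1L
  members <- members[keep]
  M <- lengths(members)
  m <- vapply(members, function(g) length(intersect(deg, g)), 0L)
  p_raw <- hypergeom_upper_p(m, n, M, N)
  p_adj <- if (params$correction == "bonferroni") bonferroni_adjust(p_raw)
           else p_raw
  out <- data.frame(pathway_id = names(members),
                    name = unname(db$names[names(members)]),
                    m = as.integer(m), n = n, M = as.integer(M), N = N,
                    percent = 100 * m / n,
                    percent_label = format_percent(m / n),
                    p_raw = p_raw, p_adj = p_adj, row.names = NULL)
  out <- out[order(out$p_raw, -out$m, out$pathway_id), ]
  rownames(out) <- NULL
  structure(out, class = c("pathway_enrichment", "data.frame"),
            n_deg = n, params = params)
}

#' @export
print.pathway_enrichment <- function(x, ...) {
  cat(sprintf(
    "Pathway over-representation: %d pathways tested, %d annotatable DEGs of %d background genes\n",
    nrow(x), attr(x, "n_deg"), if (nrow(x)) x$N[1L] else 0L))
  sig <- x$p_adj <= attr(x, "params")$alpha
  cat(sprintf("  %d pathways significant after %s correction at alpha = %g\n",
              sum(sig), attr(x, "params")$correction,
              attr(x, "params")$alpha))
  print.data.frame(head(as.data.frame(x)[c("pathway_id", "name", "m",
                                           "percent_label", "p_raw",
                                           "p_adj")], 10L),
                   row.names = FALSE)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Write an enrichment table as TSV
#'
#' @param x a `pathway_enrichment` object.
#' @param path output path.
#' @export
write_enrichment <- function(x, path) {
  write_tsv(as.data.frame(x), path)
}

# default rule deciding whether the two cooling-rate enrichments differ:
# either the fast-vs-slow contrast itself is enriched, or the slow contrast
# is strictly more significant than the fast one.
rate_difference_default <- function(p_fs, p_cf, p_cs, alpha) {
  (!is.na(p_fs) && p_fs <= alpha) ||
    (!is.na(p_cs) && !is.na(p_cf) && p_cs < p_cf)
}

#' Classify enriched pathways across the three contrasts
#'
#' Given raw enrichment p-values for one pathway in the fast-vs-slow
#' (`fs`), control-vs-fast (`cf`) and control-vs-slow (`cs`) contrasts,
#' assigns one of four types (with `sig(p)` meaning `p` present and
#' `<= alpha`):
#' \itemize{
#'   \item Type I — significant under slow cooling only
#'     (`sig(cs)` and not `sig(cf)`);
#'   \item Type II — significant under both cooling rates and more so under
#'     slow cooling (`sig(cf)`, `sig(cs)`, and a rate difference);
#'   \item Type III — significant under fast cooling only
#'     (`sig(cf)` and not `sig(cs)`);
#'   \item Type IV — significant under both rates with no rate difference;
#'   \item "none" otherwise.
#' }
#' The rate-difference rule defaults to "`sig(fs)` or `p_cs < p_cf`" and can
#' be overridden via `rate_difference`.
#'
#' @param fs,cf,cs `pathway_enrichment` objects or named numeric vectors of
#'   raw p-values keyed by pathway id; a pathway absent from a contrast has
#'   no p-value there (never significant).
#' @param alpha significance level for `sig()`.
#' @param rate_difference function `(p_fs, p_cf, p_cs, alpha) -> logical`
#'   deciding Type II vs IV for pathways significant under both rates.
#' @return Data frame with columns `pathway_id`, `p_fs`, `p_cf`, `p_cs`,
#'   `type` (factor with levels I, II, III, IV, none).
#' @export
classify_pathway_types <- function(fs, cf, cs, alpha = 0.05,
                                   rate_difference = rate_difference_default) {
  as_pvec <- function(x) {
    if (inherits(x, "pathway_enrichment"))
      return(stats::setNames(x$p_raw, x$pathway_id))
    if (is.numeric(x) && !is.null(names(x))) return(x)
    stopf("expected a pathway_enrichment object or a named numeric vector")
  }
  p_fs <- as_pvec(fs); p_cf <- as_pvec(cf); p_cs <- as_pvec(cs)
  ids <- unique(c(names(p_fs), names(p_cf), names(p_cs)))
  sig <- function(p) !is.na(p) && p <= alpha
  type <- vapply(ids, function(id) {
    pf <- unname(p_fs[id]); pc <- unname(p_cf[id]); ps <- unname(p_cs[id])
    if (sig(pc) && sig(ps)) {
      if (isTRUE(rate_difference(pf, pc, ps, alpha))) "II" else "IV"
    } else if (sig(ps)) "I"
    else if (sig(pc)) "III"
    else "none"
  }, "")
  data.frame(pathway_id = ids,
             p_fs = unname(p_fs[ids]), p_cf = unname(p_cf[ids]),
             p_cs = unname(p_cs[ids]),
             type = factor(type, levels = c("I", "II", "III", "IV", "none")),
             row.names = NULL)
}
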