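# Audic-Claverie exact test for two sequencing libraries without replicates.
#
# Conditional on observing x tags for a gene in a library of N1 total tags,
# the count y in a second library of N2 tags has, under equal expression,
#
#   p(y | x) = (N2/N1)^y * (x+y)! / ( x! * y! * (1 + N2/N1)^(x+y+1) )
#
# i.e. a negative binomial with size x+1 and success probability
# N1/(N1+N2).  Everything here works in log space via lgamma so counts in
# the tens of thousands are safe.

#' Log conditional probability of the two-library exact test
#'
#' @param y observed count(s) in the second library (non-negative integer).
#' @param x conditioning count in the first library.
#' @param n1,n2 total tag counts (library sizes) of the first and second
#'   library.
#' @return `log p(y | x)`, vectorised over `y` (and `x`).
#' @examples
#' exp(ac_log_pmf(1, 1, 1e6, 1e6))  # 2!/(1!*1!*2^3) = 0.25
#' @export
ac_log_pmf <- function(y, x, n1, n2) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(x != floor(x)) || any(y != floor(y)))
    stopf("counts must be integers")
  if (any(n1 <= 0) || any(n2 <= 0)) stopf("library sizes must be positive")
  r <- n2 / n1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

# log P(Y <= y | x): direct summation of the pmf (exact, no closed form
# needed; y' runs over at most y+1 terms).
ac_log_lower_tail <- function(x, y, n1, n2) {
  logsumexp(ac_log_pmf(0:y, x, n1, n2))
}

# log P(Y >= y | x): summed upward from y in blocks until the geometric
# remainder bound falls below rel_tol of the accumulated sum.  The term
# ratio t(k+1)/t(k) = (x+k+1)/(k+1) * q with q = r/(1+r) < 1 decreases
# towards q, so once it is < 1 the remainder is bounded by
# t(k) * rho/(1-rho).
ac_log_upper_tail <- function(x, y, n1, n2, rel_tol = 1e-15) {
  q <- (n2 / n1) / (1 + n2 / n1)
  acc <- -Inf
  k0 <- y
  block <- 256L
  repeat {
    ks <- k0:(k0 + block - 1L)
    lp <- ac_log_pmf(ks, x, n1, n2)
    acc <- logsumexp(c(acc, lp))
    klast <- ks[block]
    rho <- (x + klast + 1) / (klast + 1) * q
    if (rho < 1) {
      log_rem <- lp[block] + log(rho / (1 - rho))
      if (log_rem <= acc + log(rel_tol)) return(acc)
    }
    k0 <- k0 + block
  }
}

#' Two-sided exact p-value for differential expression of one gene
#'
#' Doubles the smaller of the two tail probabilities (both tails include
#' the observed count) and caps at 1:
#' `p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`.
#' Symmetric under relabelling: `p(x, y, N1, N2) = p(y, x, N2, N1)`.
#'
#' @param x,y counts of the gene in the two libraries (vectorised).
#' @param n1,n2 library totals.
#' @return p-value(s) in `(0, 1]`.
#' @export
ac_two_sided_p <- function(x, y, n1, n2) {
  k <- max(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  vapply(seq_len(k), function(i) {
    lo <- ac_log_lower_tail(x[i], y[i], n1[i], n2[i])
    up <- ac_log_upper_tail(x[i], y[i], n1[i], n2[i])
    min(1, 2 * exp(min(lo, up)))
  }, 0)
}

#' Log2 expression ratio between two libraries
#'
#' `log2((y*/N2) / (x*/N1))` on library-size-normalised counts, with zero
#' counts substituted by 1 (`x* = max(x, 1)`) so that a gene absent from
#' one library still yields a finite ratio.  Gene length cancels between
#' the two samples, so this equals the RPKM ratio.  Genes with zero counts
#' in both libraries have no defined ratio and must be excluded by the
#' caller ([run_contrast()] does).
#'
#' @inheritParams ac_two_sided_p
#' @return `log2` ratio(s), oriented second library over first.
#' @examples
#' log2_ratio(10, 40, 1e6, 1e6)  # 4-fold up -> 2
#' @export
log2_ratio <- function(x, y, n1, n2) {
  if (any(x == 0 & y == 0))
    stopf("log2 ratio undefined for genes with zero counts in both libraries")
  log2((pmax(y, 1) / n2) / (pmax(x, 1) / n1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q(i) = min_{j>=i} p(j) * n / j`, capped at 1,
#' in input order), computed with [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' DEG calling thresholds
#'
#' A gene is called differentially expressed when `fdr <= max_fdr` **and**
#' `|log2 ratio| >= min_abs_log2_ratio`.  The defaults (FDR <= 0.001,
#' |log2 ratio| >= 1) are the conventional joint threshold for
#' no-replicate tag-count studies.
#'
#' @param max_fdr FDR ceiling (inclusive), in (0, 1).
#' @param min_abs_log2_ratio minimum absolute log2 fold-change (inclusive).
#' @return An object of class `deg_thresholds`.
#' @export
deg_thresholds <- function(max_fdr = 0.001, min_abs_log2_ratio = 1) {
  if (max_fdr <= 0 || max_fdr >= 1) stopf("max_fdr must lie in (0, 1)")
  if (min_abs_log2_ratio < 0) stopf("min_abs_log2_ratio must be >= 0")
  structure(list(max_fdr = max_fdr,
                 min_abs_log2_ratio = min_abs_log2_ratio),
            class = "deg_thresholds")
}
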