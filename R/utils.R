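# Shared internal helpers: rounding/rendering and TSV plumbing.

# Round half away from zero (report tables render percentages this way;
# base round() rounds half to even).
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Render a proportion as a fixed two-decimal percentage string, "67.90%".
format_percent <- function(p, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"), round_half_away(100 * p, digits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
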