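# Shared builders for small in-memory fixtures.

make_counts <- function(mat, sizes = NULL) {
  count_matrix(mat, sizes)
}

# Minimal hand-built contrast object with prescribed DEG calls, for the
# set-analysis operations that only consume gene ids and directions.
fake_contrast <- function(name, genes, log2_ratio, fdr = 1e-6,
                          sample_a = "A", sample_b = "B") {
  log2_ratio <- rep_len(log2_ratio, length(genes))
  fdr <- rep_len(fdr, length(genes))
  thr <- deg_thresholds()
  direction <- ifelse(log2_ratio > 0, "up",
                      ifelse(log2_ratio < 0, "down", "flat"))
  structure(list(contrast = name, sample_a = sample_a, sample_b = sample_b,
                 n1 = 1e6, n2 = 1e6, thresholds = thr, n_excluded = 0L,
                 table = data.frame(gene_id = genes,
                                    x = rep_len(1L, length(genes)),
                                    y = rep_len(1L, length(genes)),
                                    log2_ratio = log2_ratio, p = fdr,
                                    fdr = fdr, direction = direction,
                                    is_deg = fdr <= thr$max_fdr &
                                      abs(log2_ratio) >=
                                        thr$min_abs_log2_ratio,
                                    row.names = NULL)),
            class = "ac_contrast")
}

# The reference simulation scenario used across recovery tests.
reference_spec <- function(seed = 1L) {
  experiment_spec(n_genes = 5000L,
                  library_sizes = c(control = 1e6, fast = 1e6, slow = 1e6),
                  baseline_mean = 50, dispersion = 0,
                  planted = c(shared_up = 100L, shared_down = 100L,
                              opposite = 20L),
                  fold_change = 4,
                  planted_enriched = list(list(pathway = 1L,
                                               class = "shared_up",
                                               factor = 10)),
                  seed = seed)
}

extdata <- function(f) system.file("extdata", f, package = "coolseq")

# Naive Benjamini-Hochberg step-up, straight from the definition.
bh_naive <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Exhaustive-enumeration hypergeometric upper tail: enumerate every n-subset
# of an N-gene universe whose first M genes are pathway members.
hyper_enum <- function(m, n, M, N) {
  if (n == 0) return(if (m == 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= m)
}
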