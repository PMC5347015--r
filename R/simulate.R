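#' Specification of a synthetic three-library experiment
#'
#' Describes a control / fast-cooled / slow-cooled count experiment with
#' planted ground truth.  The defaults emulate a HiSeq-era lettuce-seed
#' cooling study: three libraries whose totals match typical uniquely
#' mapped read counts (~7.5-8.4 million), ~20,000 genes, log-normal
#' baseline expression and Poisson count noise.
#'
#' Per-gene expected counts are drawn log-normal around `baseline_mean`
#' (shape parameter `baseline_sigma` on the log scale), multiplied by the
#' planted per-sample fold-changes, then rescaled per sample so the
#' expected column sum equals the requested library size; counts are drawn
#' Poisson (`dispersion = 0`) or negative binomial with variance
#' `mu + dispersion * mu^2`.
#'
#' Planted DEG classes mirror the structure of a two-cooling-rate design:
#' `shared_up` / `shared_down` respond identically to both cooling rates
#' (cold-responsive genes), `fast_only` / `slow_only` respond to one rate,
#' and `opposite` genes go up under fast cooling and down under slow
#' cooling (both relative to control).
#'
#' @param n_genes number of genes.
#' @param library_sizes named numeric vector of three library totals
#'   (control, fast, slow).
#' @param baseline_mean mean expected count per gene before rescaling.
#' @param baseline_sigma sdlog of the log-normal baseline draw.
#' @param dispersion negative-binomial over-dispersion; 0 means Poisson.
#' @param gene_length_range integer range (min, max) of gene lengths in bp.
#' @param planted named integer vector/list of planted gene counts per
#'   class: `shared_up`, `shared_down`, `fast_only`, `slow_only`,
#'   `opposite` (missing entries default to 0).
#' @param fold_change planted fold-change (>= 1), applied per class.
#' @param n_pathways number of annotation pathways.
#' @param pathway_size_range integer range of pathway sizes.
#' @param planted_enriched list of `list(pathway = <index or id>, class =
#'   <DEG class>, factor = <sampling enrichment factor>)` entries; member
#'   sampling weights genes of the class by `factor`.
#' @param seed integer seed governing all randomness.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(n_genes = 20000L,
                            library_sizes = c(control = 8350513,
                                              fast = 7651551,
                                              slow = 7505842),
                            baseline_mean = 50, baseline_sigma = 1,
                            dispersion = 0,
                            gene_length_range = c(200L, 5000L),
                            planted = c(shared_up = 0L, shared_down = 0L,
                                        fast_only = 0L, slow_only = 0L,
                                        opposite = 0L),
                            fold_change = 4,
                            n_pathways = 50L,
                            pathway_size_range = c(10L, 60L),
                            planted_enriched = list(),
                            seed = 1L) {
  classes <- c("shared_up", "shared_down", "fast_only", "slow_only",
               "opposite")
  pl <- stats::setNames(integer(5L), classes)
  planted <- unlist(planted)
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% classes))
      stopf("planted classes must be among: %s", paste(classes, collapse = ", "))
    pl[names(planted)] <- as.integer(planted)
  }
  if (sum(pl) > n_genes) stopf("more planted genes than genes")
  if (fold_change < 1) stopf("fold_change must be >= 1")
  if (length(library_sizes) != 3L || any(library_sizes <= 0))
    stopf("library_sizes must be three positive totals")
  if (is.null(names(library_sizes)))
    names(library_sizes) <- c("control", "fast", "slow")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  for (pe in planted_enriched)
    if (!all(c("pathway", "class", "factor") %in% names(pe)))
      stopf("each planted_enriched entry needs pathway, class and factor")
  structure(list(n_genes = as.integer(n_genes),
                 library_sizes = library_sizes,
                 baseline_mean = baseline_mean,
                 baseline_sigma = baseline_sigma,
                 dispersion = dispersion,
                 gene_length_range = as.integer(gene_length_range),
                 planted = pl, fold_change = fold_change,
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 planted_enriched = planted_enriched,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Generate a synthetic experiment with known truth
#'
#' Draws gene lengths, baseline means, planted fold-changes, counts and a
#' pathway annotation from an [experiment_spec()].  The returned count
#' matrix carries the realised column sums as library sizes (every
#' simulated read maps uniquely to a counted gene).  Identical spec and
#' seed give identical output.
#'
#' @param spec an [experiment_spec()].
#' @return A list with elements `counts` ([count_matrix()]), `lengths`
#'   (named integer vector), `pathways` ([pathway_db()]) and `truth`
#'   (class `truth_bundle`: per-gene classes and true per-contrast folds,
#'   per-pathway planted-enrichment table, and the spec).
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  gene_id <- sprintf("g%05d", seq_len(ng))
  lengths <- stats::setNames(
    sample(spec$gene_length_range[1L]:spec$gene_length_range[2L], ng,
           replace = TRUE), gene_id)
  mu0 <- rlnorm(ng, meanlog = log(spec$baseline_mean) -
                  spec$baseline_sigma^2 / 2, sdlog = spec$baseline_sigma)

  class <- rep("null", ng)
  idx <- sample.int(ng, sum(spec$planted))
  off <- 0L
  for (cl in names(spec$planted)) {
    k <- spec$planted[[cl]]
    if (k > 0L) class[idx[off + seq_len(k)]] <- cl
    off <- off + k
  }
  f <- spec$fold_change
  # per-sample expression multipliers relative to control
  mult_fast <- ifelse(class %in% c("shared_up", "fast_only", "opposite"), f,
                      ifelse(class == "shared_down", 1 / f, 1))
  mult_slow <- ifelse(class %in% c("shared_up", "slow_only"), f,
                      ifelse(class %in% c("shared_down", "opposite"), 1 / f, 1))
  mult <- cbind(control = rep(1, ng), fast = mult_fast, slow = mult_slow)

  counts <- matrix(0L, ng, 3L,
                   dimnames = list(gene_id, names(spec$library_sizes)))
  for (j in 1:3) {
    mu <- mu0 * mult[, j]
    mu <- mu * spec$library_sizes[[j]] / sum(mu)
    counts[, j] <- if (spec$dispersion == 0) rpois(ng, mu)
                   else rnbinom(ng, mu = mu, size = 1 / spec$dispersion)
  }

  # pathway annotation with optional planted enrichment
  pw_id <- sprintf("pw%03d", seq_len(spec$n_pathways))
  sizes <- sample(spec$pathway_size_range[1L]:spec$pathway_size_range[2L],
                  spec$n_pathways, replace = TRUE)
  planted_pw <- data.frame(pathway_id = pw_id, planted = FALSE,
                           class = NA_character_, factor = NA_real_)
  weights <- matrix(1, ng, spec$n_pathways)
  for (pe in spec$planted_enriched) {
    k <- if (is.character(pe$pathway)) match(pe$pathway, pw_id)
         else as.integer(pe$pathway)
    if (is.na(k) || k < 1L || k > spec$n_pathways)
      stopf("planted_enriched refers to unknown pathway")
    weights[class == pe$class, k] <- pe$factor
    planted_pw$planted[k] <- TRUE
    planted_pw$class[k] <- pe$class
    planted_pw$factor[k] <- pe$factor
  }
  members <- lapply(seq_len(spec$n_pathways), function(k) {
    gene_id[sample.int(ng, sizes[k], prob = weights[, k])]
  })
  names(members) <- pw_id
  db <- pathway_db(members,
                   stats::setNames(sprintf("Synthetic pathway %d",
                                           seq_len(spec$n_pathways)), pw_id))

  truth <- structure(
    list(genes = data.frame(gene_id = gene_id, class = class,
                            fold_fast = mult[, "fast"],
                            fold_slow = mult[, "slow"],
                            row.names = NULL),
         pathways = planted_pw, spec = spec),
    class = "truth_bundle")
  list(counts = count_matrix(counts), lengths = lengths, pathways = db,
       truth = truth)
}

#' Generate a toy FASTQ batch with planted filter failures
#'
#' Builds `n_reads` reads of length `read_len` in which exactly the planted
#' number of reads violates each clean-read rule and no other: adapter
#' reads carry one exact adapter insertion (and are otherwise clean),
#' N-heavy reads have 20% N bases, low-quality reads have 60% of bases at
#' Phred 3; all remaining reads are N-free, adapter-free and high quality.
#' Categories are mutually exclusive by construction, so
#' [filter_fastq()] must report exactly the planted tallies.
#'
#' @param n_reads total reads.
#' @param read_len read length in bases.
#' @param planted named vector with entries `adapter`, `n_fraction`,
#'   `low_quality` (missing entries default to 0); their sum must not
#'   exceed `n_reads`.
#' @param adapters adapter sequence(s); the first is inserted into planted
#'   adapter reads.
#' @param seed integer seed.
#' @return A data frame with columns `read_id`, `sequence`, `quality`,
#'   `truth` (one of clean/adapter/n_fraction/low_quality), in shuffled
#'   order.
#' @export
generate_fastq <- function(n_reads, read_len = 50L,
                           planted = c(adapter = 0L, n_fraction = 0L,
                                       low_quality = 0L),
                           adapters = "AGATCGGAAGAGC", seed = 1L) {
  pl <- stats::setNames(integer(3L), c("adapter", "n_fraction", "low_quality"))
  planted <- unlist(planted)
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% names(pl)))
      stopf("planted categories must be adapter, n_fraction, low_quality")
    pl[names(planted)] <- as.integer(planted)
  }
  if (sum(pl) > n_reads) stopf("more planted failures than reads")
  ad <- adapters[1L]
  if (read_len < nchar(ad)) stopf("read_len shorter than the adapter")
  set.seed(seed)
  rand_seq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }
  clean_seq <- function() {
    repeat {
      s <- rand_seq(read_len)
      if (!any(contains_adapter(s, adapters))) return(s)
    }
  }
  hi_qual <- function() {
    paste(sample(strsplit("?@ABCDEFGHI", "")[[1L]], read_len,
                 replace = TRUE), collapse = "")  # Phred 30-40
  }
  truth <- rep(c("adapter", "n_fraction", "low_quality", "clean"),
               c(pl, n_reads - sum(pl)))
  seqs <- character(n_reads); quals <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (truth[i] == "adapter") {
      s <- clean_seq()
      pos <- sample.int(read_len - nchar(ad) + 1L, 1L)
      substr(s, pos, pos + nchar(ad) - 1L) <- ad
      seqs[i] <- s; quals[i] <- hi_qual()
    } else if (truth[i] == "n_fraction") {
      s <- clean_seq()
      k <- ceiling(0.2 * read_len)
      pos <- sample.int(read_len, k)
      for (p in pos) substr(s, p, p) <- "N"
      seqs[i] <- s; quals[i] <- hi_qual()
    } else if (truth[i] == "low_quality") {
      seqs[i] <- clean_seq()
      q <- strsplit(hi_qual(), "")[[1L]]
      q[sample.int(read_len, ceiling(0.6 * read_len))] <- "$"  # Phred 3
      quals[i] <- paste(q, collapse = "")
    } else {
      seqs[i] <- clean_seq(); quals[i] <- hi_qual()
    }
  }
  ord <- sample.int(n_reads)
  data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
             sequence = seqs[ord], quality = quals[ord],
             truth = truth[ord], row.names = NULL)
}

#' Recovery metrics against planted truth
#'
#' Compares DEG calls (and optionally enrichment results) with the planted
#' truth of a generated experiment.  Per planted class, sensitivity is the
#' fraction of planted genes recovered as DEGs in every contrast where the
#' class has a true effect (`shared_*`: both control contrasts; `fast_only`
#' / `slow_only`: the corresponding contrast; `opposite`: both, with
#' opposite directions).  Per contrast, the observed FDR is the fraction of
#' DEG calls on genes whose true fold for that contrast is 1 (0/0 counts as
#' 0).
#'
#' @param cf,cs `ac_contrast` objects for control-vs-fast and
#'   control-vs-slow, computed from the truth's experiment.
#' @param truth the `truth_bundle` of [generate_experiment()].
#' @param enrichment optional named list of `pathway_enrichment` objects;
#'   for each planted-enriched pathway its rank by raw p in each table is
#'   reported.
#' @return A list with `per_class`, `per_contrast`, `opposite`
#'   (data frames) and optionally `pathway_ranks`.
#' @export
evaluate_recovery <- function(cf, cs, truth, enrichment = NULL) {
  stopifnot(inherits(cf, "ac_contrast"), inherits(cs, "ac_contrast"),
            inherits(truth, "truth_bundle"))
  g <- truth$genes
  if (!all(cf$table$gene_id %in% g$gene_id) ||
      !all(cs$table$gene_id %in% g$gene_id))
    stopf("contrast gene ids do not match the truth bundle")
  deg_cf <- deg_ids(cf); deg_cs <- deg_ids(cs)
  recovered <- function(cl) {
    ids <- g$gene_id[g$class == cl]
    hit <- switch(cl,
      shared_up = , shared_down = ids %in% deg_cf & ids %in% deg_cs,
      fast_only = ids %in% deg_cf,
      slow_only = ids %in% deg_cs,
      opposite = {
        opp <- opposite_direction(cf, cs)
        ids %in% opp$gene_id
      })
    c(planted = length(ids), recovered = sum(hit))
  }
  classes <- c("shared_up", "shared_down", "fast_only", "slow_only",
               "opposite")
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    r <- recovered(cl)
    data.frame(class = cl, planted = r[["planted"]],
               recovered = r[["recovered"]],
               sensitivity = if (r[["planted"]]) r[["recovered"]] /
                 r[["planted"]] else NA_real_)
  }))
  obs_fdr <- function(ct, fold_col) {
    calls <- deg_ids(ct)
    if (!length(calls)) return(c(calls = 0, false = 0, fdr = 0))
    truefold <- g[[fold_col]][match(calls, g$gene_id)]
    c(calls = length(calls), false = sum(truefold == 1),
      fdr = mean(truefold == 1))
  }
  fc <- obs_fdr(cf, "fold_fast"); sc <- obs_fdr(cs, "fold_slow")
  per_contrast <- data.frame(
    contrast = c(cf$contrast, cs$contrast),
    calls = c(fc[["calls"]], sc[["calls"]]),
    false_calls = c(fc[["false"]], sc[["false"]]),
    observed_fdr = c(fc[["fdr"]], sc[["fdr"]]))
  opp <- opposite_direction(cf, cs)
  planted_opp <- g$gene_id[g$class == "opposite"]
  opposite <- data.frame(planted = length(planted_opp),
                         flagged = nrow(opp),
                         recovered = sum(planted_opp %in% opp$gene_id))
  out <- list(per_class = per_class, per_contrast = per_contrast,
              opposite = opposite)
  if (!is.null(enrichment)) {
    planted_pw <- truth$pathways[truth$pathways$planted, "pathway_id"]
    out$pathway_ranks <- do.call(rbind, lapply(names(enrichment), function(nm) {
      e <- enrichment[[nm]]
      data.frame(table = nm, pathway_id = planted_pw,
                 rank = match(planted_pw, e$pathway_id))
    }))
  }
  out
}
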