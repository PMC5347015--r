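#' Assemble a pipeline configuration
#'
#' A flat key-value configuration for [run_pipeline()].  It can also be
#' loaded from a YAML file with [read_pipeline_config()].  Recognised keys:
#'
#' \describe{
#'   \item{counts}{path to the count-table TSV (required).}
#'   \item{gene_lengths}{path to the two-column gene-length TSV (required).}
#'   \item{pathways}{path to a GMT or gene-to-pathway TSV (required).}
#'   \item{fastq}{optional FASTQ path; when given, clean-read filtering
#'     runs first and writes the clean FASTQ plus a QC report.}
#'   \item{adapters}{adapter sequences for the QC stage.}
#'   \item{max_n_fraction, low_quality_phred, max_low_quality_fraction,
#'     phred_offset}{QC thresholds, see [qc_params()].}
#'   \item{max_fdr, min_abs_log2_ratio}{DEG thresholds, see
#'     [deg_thresholds()].}
#'   \item{alpha, correction}{enrichment significance settings, see
#'     [enrichment_params()].}
#'   \item{contrasts}{list of two-element sample-id pairs; defaults to
#'     control/fast, control/slow, fast/slow.}
#'   \item{outdir}{output directory (required).}
#' }
#'
#' @param ... configuration keys as named arguments.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  defaults <- list(adapters = character(), max_n_fraction = 0.10,
                   low_quality_phred = 5L, max_low_quality_fraction = 0.50,
                   phred_offset = 33L, max_fdr = 0.001,
                   min_abs_log2_ratio = 1, alpha = 0.05,
                   correction = "bonferroni",
                   contrasts = list(c("control", "fast"),
                                    c("control", "slow"),
                                    c("fast", "slow")))
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  for (k in c("counts", "gene_lengths", "pathways", "outdir"))
    if (is.null(cfg[[k]])) stopf("pipeline config is missing '%s'", k)
  structure(cfg, class = "pipeline_config")
}

#' @param path YAML file of configuration keys.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: clean-read filtering (if a FASTQ is configured),
#' RPKM quantification, the three pairwise exact-test contrasts, DEG Venn
#' bookkeeping, the opposite-direction gene table, per-contrast pathway
#' enrichment, and the Type I-IV pathway classification.  All inputs are
#' validated (files exist, contrast samples present) before any output is
#' written; any stage failure aborts with an error naming the stage.
#' Every output is a TSV in `outdir`, listed with its MD5 checksum in
#' `manifest.tsv`; given identical inputs and configuration the checksums
#' are identical across runs.
#'
#' @param config a [pipeline_config()] or the path to a YAML config file.
#' @param quiet suppress per-stage log messages.
#' @return Invisibly, a list with `manifest` (data frame of file, md5) and
#'   the per-stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- "validation"
  fail <- function(e) stopf("pipeline stage '%s' failed: %s", stage,
                            conditionMessage(e))
  tryCatch({
    for (k in c("counts", "gene_lengths", "pathways"))
      if (!file.exists(config[[k]]))
        stopf("input file for '%s' not found: %s", k, config[[k]])
    if (!is.null(config$fastq) && !file.exists(config$fastq))
      stopf("FASTQ file not found: %s", config$fastq)
    counts <- read_count_table(config$counts)
    lengths <- read_gene_lengths(config$gene_lengths)
    db <- read_pathway_db(config$pathways)
    for (ct in config$contrasts)
      for (s in ct)
        if (!s %in% colnames(counts$counts))
          stopf("contrast sample '%s' missing from the count table", s)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  }, error = fail)
  out <- function(f) file.path(config$outdir, f)
  files <- character()
  results <- list()

  if (!is.null(config$fastq)) {
    stage <- "qc"
    tryCatch({
      qp <- qc_params(config$adapters, config$max_n_fraction,
                      config$low_quality_phred,
                      config$max_low_quality_fraction, config$phred_offset)
      fq <- filter_fastq(config$fastq, qp)
      write_fastq(fq$kept, out("clean_reads.fastq"))
      write_tsv(as.data.frame(fq$report), out("qc_report.tsv"))
      files <- c(files, "clean_reads.fastq", "qc_report.tsv")
      results$qc <- fq$report
      log("qc: %d reads in, %d kept", fq$report$n_input, fq$report$n_kept)
    }, error = fail)
  }

  stage <- "quantify"
  tryCatch({
    expr <- rpkm_matrix(counts, lengths)
    write_expression_matrix(expr, out("expression_rpkm.tsv"))
    files <- c(files, "expression_rpkm.tsv")
    results$expression <- expr
    log("quantify: RPKM for %d genes x %d samples", nrow(expr), ncol(expr))
  }, error = fail)

  stage <- "de"
  tryCatch({
    thr <- deg_thresholds(config$max_fdr, config$min_abs_log2_ratio)
    contrasts <- lapply(config$contrasts, function(ct) {
      run_contrast(counts, ct[1L], ct[2L], thr)
    })
    names(contrasts) <- vapply(contrasts, `[[`, "", "contrast")
    for (ct in contrasts) {
      f <- sprintf("contrast_%s.tsv", ct$contrast)
      write_contrast(ct, out(f))
      files <- c(files, f)
      s <- summary(ct)
      log("de: %s -> %d DEGs (%d up, %d down)", ct$contrast, s$total, s$up,
          s$down)
    }
    results$contrasts <- contrasts
  }, error = fail)

  stage <- "venn"
  tryCatch({
    vc <- venn_counts(results$contrasts)
    write_tsv(vc$per_contrast, out("deg_venn.tsv"))
    write_tsv(vc$intersections, out("deg_venn_intersections.tsv"))
    files <- c(files, "deg_venn.tsv", "deg_venn_intersections.tsv")
    results$venn <- vc
  }, error = fail)

  stage <- "opposite"
  tryCatch({
    ref <- results$contrasts[vapply(config$contrasts, function(ct)
      ct[1L] == config$contrasts[[1L]][1L], TRUE)]
    opp <- if (length(ref) >= 2L)
      opposite_direction(ref[[1L]], ref[[2L]])
    else data.frame(gene_id = character(), dir_a = character(),
                    dir_b = character())
    write_tsv(opp, out("opposite_direction.tsv"))
    files <- c(files, "opposite_direction.tsv")
    results$opposite <- opp
    log("opposite: %d genes flagged", nrow(opp))
  }, error = fail)

  stage <- "enrich"
  tryCatch({
    ep <- enrichment_params(config$alpha, config$correction)
    enr <- lapply(results$contrasts, function(ct) {
      enrich(deg_ids(ct), db, params = ep)
    })
    for (nm in names(enr)) {
      f <- sprintf("enrichment_%s.tsv", nm)
      write_enrichment(enr[[nm]], out(f))
      files <- c(files, f)
      log("enrich: %s -> %d pathways tested", nm, nrow(enr[[nm]]))
    }
    results$enrichment <- enr
  }, error = fail)

  stage <- "classify"
  tryCatch({
    cts <- config$contrasts
    pick <- function(a, b) {
      i <- which(vapply(cts, function(ct) ct[1L] == a && ct[2L] == b, TRUE))
      if (!length(i)) stopf("no %s/%s contrast configured", a, b)
      results$enrichment[[i]]
    }
    fs <- pick(cts[[3L]][1L], cts[[3L]][2L])
    cf <- pick(cts[[1L]][1L], cts[[1L]][2L])
    cs <- pick(cts[[2L]][1L], cts[[2L]][2L])
    typing <- classify_pathway_types(fs, cf, cs, alpha = config$alpha)
    write_tsv(typing, out("pathway_types.tsv"))
    files <- c(files, "pathway_types.tsv")
    results$types <- typing
    log("classify: %d pathways typed", nrow(typing))
  }, error = fail)

  manifest <- data.frame(file = files,
                         md5 = unname(md5sum(vapply(files, out, ""))))
  write_tsv(manifest, out("manifest.tsv"))
  log("pipeline complete: %d artifacts in %s", nrow(manifest), config$outdir)
  invisible(c(list(manifest = manifest), results))
}
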