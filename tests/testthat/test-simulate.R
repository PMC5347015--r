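test_that("generation is deterministic given spec and seed", {
  spec <- experiment_spec(n_genes = 400L,
                          library_sizes = c(control = 1e5, fast = 1e5,
                                            slow = 1e5),
                          planted = c(shared_up = 20L, opposite = 5L),
                          n_pathways = 8L, seed = 123)
  a <- generate_experiment(spec)
  b <- generate_experiment(spec)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$pathways$members, b$pathways$members)
  expect_identical(a$truth$genes, b$truth$genes)
  # FASTQ generation: identical bytes for identical seeds
  f1 <- generate_fastq(60, planted = c(adapter = 4), seed = 9)
  f2 <- generate_fastq(60, planted = c(adapter = 4), seed = 9)
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_fastq(f1, t1); write_fastq(f2, t2)
  expect_identical(readLines(t1), readLines(t2))
  f3 <- generate_fastq(60, planted = c(adapter = 4), seed = 10)
  expect_false(identical(f1$sequence, f3$sequence))
})

test_that("a spec without planted effects labels every gene null", {
  ex <- generate_experiment(experiment_spec(
    n_genes = 200L, library_sizes = c(control = 5e4, fast = 5e4, slow = 5e4),
    n_pathways = 5L, seed = 2))
  expect_true(all(ex$truth$genes$class == "null"))
  expect_true(all(ex$truth$genes$fold_fast == 1))
})

test_that("column sums track declared library sizes and planted folds recover", {
  spec <- experiment_spec(n_genes = 3000L,
                          library_sizes = c(control = 8e5, fast = 8e5,
                                            slow = 8e5),
                          baseline_mean = 60, dispersion = 0,
                          planted = c(shared_up = 100L), fold_change = 4,
                          n_pathways = 10L, seed = 31)
  ex <- generate_experiment(spec)
  cs <- colSums(ex$counts$counts)
  expect_true(all(abs(cs - 8e5) / 8e5 < 0.05))
  expect_equal(unname(ex$counts$library_sizes), unname(cs))
  g <- ex$truth$genes
  up <- g$class == "shared_up"
  # empirical fold of planted genes, using null genes to cancel the
  # per-column rescaling that keeps library totals fixed
  r_planted <- sum(ex$counts$counts[up, "fast"]) /
    sum(ex$counts$counts[up, "control"])
  r_null <- sum(ex$counts$counts[!up, "fast"]) /
    sum(ex$counts$counts[!up, "control"])
  expect_equal(r_planted / r_null, 4, tolerance = 0.10)
})

test_that("infeasible specs are rejected", {
  expect_error(experiment_spec(n_genes = 10L,
                               planted = c(shared_up = 11L)),
               "more planted genes")
  expect_error(experiment_spec(fold_change = 0.5), "fold_change")
  expect_error(generate_fastq(5, planted = c(adapter = 6)),
               "more planted failures")
  expect_error(experiment_spec(planted = c(bogus_class = 3L)), "classes")
})

test_that("planted FASTQ failures are exact and mutually exclusive", {
  fq <- generate_fastq(100, read_len = 50,
                       planted = c(adapter = 7, n_fraction = 5,
                                   low_quality = 3),
                       seed = 77)
  # independent direct scan of each rule
  ad <- contains_adapter(fq$sequence, "AGATCGGAAGAGC")
  nf <- fraction_n(fq$sequence) > 0.10
  lq <- fraction_low_quality(fq$quality) > 0.50
  expect_equal(sum(ad), 7L)
  expect_equal(sum(nf & !ad), 5L)
  expect_equal(sum(lq & !ad & !nf), 3L)
  expect_equal(sum(ad & nf), 0L)  # categories never overlap
  expect_equal(sum(ad & lq), 0L)
  expect_equal(sum(nf & lq), 0L)
  # zero planted failures -> everything kept
  clean <- generate_fastq(30, planted = c(), seed = 5)
  res <- filter_fastq(clean, qc_params(adapters = "AGATCGGAAGAGC"))
  expect_equal(res$report$n_kept, 30L)
})

test_that("recovery metrics honour their conventions", {
  ex <- generate_experiment(experiment_spec(
    n_genes = 300L, library_sizes = c(control = 1e5, fast = 1e5, slow = 1e5),
    planted = c(shared_up = 10L, opposite = 4L), fold_change = 4,
    n_pathways = 5L, seed = 6))
  g <- ex$truth$genes
  # perfect caller: DEG exactly where the truth has an effect
  perfect <- function(name, fold_col) {
    eff <- g[[fold_col]] != 1
    fake_contrast(name, g$gene_id[eff],
                  ifelse(g[[fold_col]][eff] > 1, 2, -2))
  }
  cf <- perfect("control_vs_fast", "fold_fast")
  cs <- perfect("control_vs_slow", "fold_slow")
  rec <- evaluate_recovery(cf, cs, ex$truth)
  expect_equal(rec$per_class$sensitivity[rec$per_class$class == "shared_up"], 1)
  expect_equal(rec$per_class$sensitivity[rec$per_class$class == "opposite"], 1)
  expect_equal(rec$per_contrast$observed_fdr, c(0, 0))
  # no calls at all: sensitivity 0, observed FDR 0 by the 0/0 convention
  none <- fake_contrast("control_vs_fast", character(0), numeric(0))
  none2 <- fake_contrast("control_vs_slow", character(0), numeric(0))
  rec0 <- evaluate_recovery(none, none2, ex$truth)
  expect_equal(rec0$per_class$sensitivity[rec0$per_class$class == "shared_up"], 0)
  expect_equal(rec0$per_contrast$observed_fdr, c(0, 0))
  # foreign gene ids are rejected
  alien <- fake_contrast("control_vs_fast", "not_a_gene", 2)
  expect_error(evaluate_recovery(alien, cs, ex$truth), "gene ids")
})
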