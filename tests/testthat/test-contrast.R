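test_that("identical libraries yield zero DEGs", {
  set.seed(2)
  x <- rpois(300, 80)
  m <- matrix(c(x, x), ncol = 2,
              dimnames = list(sprintf("g%03d", 1:300), c("a", "b")))
  ct <- run_contrast(count_matrix(m), "a", "b", totals = c(1e6, 1e6))
  expect_equal(sum(ct$table$is_deg), 0L)
  expect_true(all(ct$table$log2_ratio == 0))
})

test_that("planted 8-fold genes all pass both thresholds, per-gene oracle agrees", {
  set.seed(9)
  n <- 1000
  x <- rpois(n, 100)
  y <- rpois(n, 100)
  planted <- 1:20
  y[planted] <- rpois(20, 800)
  m <- matrix(c(x, y), ncol = 2,
              dimnames = list(sprintf("g%04d", 1:n), c("a", "b")))
  ct <- run_contrast(count_matrix(m), "a", "b", totals = c(1e6, 1e6))
  tab <- ct$table
  expect_true(all(tab$is_deg[match(sprintf("g%04d", planted), tab$gene_id)]))
  # per-gene oracle: p from negative-binomial tails, ratio by hand
  i <- match(sprintf("g%04d", planted), tab$gene_id)
  pr <- 0.5
  lower <- pnbinom(tab$y[i], size = tab$x[i] + 1, prob = pr)
  upper <- pnbinom(tab$y[i] - 1, size = tab$x[i] + 1, prob = pr,
                   lower.tail = FALSE)
  expect_equal(tab$p[i], pmin(1, 2 * pmin(lower, upper)), tolerance = 1e-9)
  expect_equal(tab$log2_ratio[i],
               log2(pmax(tab$y[i], 1) / pmax(tab$x[i], 1)))
})

test_that("DEG calling is the conjunction of FDR and fold thresholds", {
  # large counts: tiny p, but ratio below 2-fold
  x <- c(20000L, 100L); y <- c(28000L, 100L)
  m <- matrix(c(x, y), ncol = 2,
              dimnames = list(c("strong_small_fc", "null"), c("a", "b")))
  ct <- run_contrast(count_matrix(m), "a", "b", totals = c(1e6, 1e6))
  tab <- ct$table
  expect_lt(tab$fdr[1], 1e-4)
  expect_lt(abs(tab$log2_ratio[1]), 1)
  expect_false(tab$is_deg[1])
})

test_that("tightening either threshold never adds DEGs", {
  ex <- generate_experiment(experiment_spec(
    n_genes = 800L, library_sizes = c(control = 2e5, fast = 2e5, slow = 2e5),
    planted = c(shared_up = 40L, shared_down = 40L), fold_change = 4,
    n_pathways = 10L, seed = 4))
  base <- deg_ids(run_contrast(ex$counts, "control", "fast"))
  for (thr in list(deg_thresholds(1e-4, 1), deg_thresholds(1e-3, 1.5),
                   deg_thresholds(1e-5, 2))) {
    got <- deg_ids(run_contrast(ex$counts, "control", "fast", thr))
    expect_true(all(got %in% base))
  }
})

test_that("double-zero genes are excluded and unknown samples rejected", {
  m <- matrix(c(0L, 10L, 0L, 20L), 2,
              dimnames = list(c("gz", "g1"), c("a", "b")))
  ct <- run_contrast(count_matrix(m), "a", "b", totals = c(100, 100))
  expect_equal(ct$n_excluded, 1L)
  expect_equal(ct$table$gene_id, "g1")
  expect_error(run_contrast(count_matrix(m), "a", "nope"),
               "unknown sample 'nope'")
})

test_that("contrast tables round-trip as TSV with library totals", {
  m <- matrix(c(5L, 50L, 9L, 11L), 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  ct <- run_contrast(count_matrix(m), "a", "b", totals = c(1e4, 2e4))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_contrast(ct, tf)
  back <- read.delim(tf)
  expect_equal(back$N1, rep(1e4, 2))
  expect_equal(back$p, ct$table$p)
  expect_equal(back$direction, ct$table$direction)
})

test_that("shared and opposite DEG set operations follow set algebra", {
  a <- fake_contrast("c_vs_f", c("g1", "g2", "g3"), c(2, -2, 1.5))
  b <- fake_contrast("c_vs_s", c("g2", "g3", "g4"), c(-2, -1.5, 2))
  expect_equal(sort(shared_degs(a, b)), c("g2", "g3"))
  opp <- opposite_direction(a, b)
  expect_equal(opp$gene_id, "g3")       # up in a, down in b
  expect_equal(opp$dir_a, "up")
  # same direction in both -> not flagged
  expect_false("g2" %in% opp$gene_id)
  # disjoint DEG sets
  d <- fake_contrast("x", "g9", 3)
  expect_equal(shared_degs(a, d), character())
  # identical tables share their full DEG set
  expect_equal(sort(shared_degs(a, a)), c("g1", "g2", "g3"))
})

test_that("the twelve published opposite-direction genes are all flagged", {
  pub <- read.delim(extdata("published_opposite_genes.tsv"))
  cf <- fake_contrast("control_vs_fast", pub$gene_id, pub$log2_ratio_fast,
                      pub$fdr_fast)
  cs <- fake_contrast("control_vs_slow", pub$gene_id, pub$log2_ratio_slow,
                      pub$fdr_slow)
  opp <- opposite_direction(cf, cs)
  expect_equal(nrow(opp), 12L)
  expect_setequal(opp$gene_id, pub$gene_id)
  lan <- opp[opp$gene_id == "gi|90503171", ]
  expect_equal(lan$dir_a, "down")  # down on fast cooling, up on slow
  expect_equal(lan$dir_b, "up")
})

test_that("venn bookkeeping matches direct set computation", {
  a <- fake_contrast("A", sprintf("g%02d", 1:10),
                     c(rep(2, 6), rep(-2, 4)))
  b <- fake_contrast("B", sprintf("g%02d", 6:13), rep(2, 8))
  c3 <- fake_contrast("C", character(0), numeric(0))
  vc <- venn_counts(a, b, c3)
  expect_equal(vc$per_contrast$total, c(10L, 8L, 0L))
  expect_equal(vc$per_contrast$up, c(6L, 8L, 0L))
  expect_equal(vc$per_contrast$down, c(4L, 0L, 0L))
  expect_true(all(vc$per_contrast$up + vc$per_contrast$down ==
                    vc$per_contrast$total))
  ab <- vc$intersections$shared[vc$intersections$contrast_a == "A" &
                                  vc$intersections$contrast_b == "B"]
  expect_equal(ab, length(intersect(deg_ids(a), deg_ids(b))))
  expect_equal(sum(vc$intersections$shared[vc$intersections$contrast_b == "C"]),
               0L)
})
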