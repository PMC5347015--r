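test_that("hypergeometric upper tail matches enumeration and closed cases", {
  expect_equal(hypergeom_upper_p(0, 5, 4, 10), 1)
  expect_equal(hypergeom_upper_p(3, 5, 4, 10), 66 / 252)
  expect_equal(hypergeom_upper_p(6, 6, 6, 6), 1)  # degenerate certainty
  # spot enumeration (full N <= 12 scan lives in the acceptance suite)
  for (cfg in list(c(2, 4, 5, 9), c(1, 3, 2, 7), c(4, 6, 8, 12))) {
    expect_equal(hypergeom_upper_p(cfg[1], cfg[2], cfg[3], cfg[4]),
                 hyper_enum(cfg[1], cfg[2], cfg[3], cfg[4]))
  }
  # monotone non-increasing in m
  p <- hypergeom_upper_p(0:5, 5, 40, 100)
  expect_true(all(diff(p) <= 0))
  expect_error(hypergeom_upper_p(6, 5, 10, 20), "min\\(n, M\\)")
  expect_error(hypergeom_upper_p(1, 25, 10, 20), "exceed N")
})

test_that("bonferroni adjustment multiplies by test count and caps at one", {
  expect_equal(bonferroni_adjust(0.01), 0.01)
  expect_equal(bonferroni_adjust(c(0.01, 0.4)), c(0.02, 0.8))
  expect_equal(bonferroni_adjust(c(0.6, 0.9)), c(1, 1))
})

test_that("enrichment rows carry exact overlap counts and sort by p", {
  db <- pathway_db(list(hit = sprintf("g%02d", 1:10),
                        miss = sprintf("g%02d", 40:49),
                        part = sprintf("g%02d", c(1:3, 50:56))))
  universe <- sprintf("g%02d", 1:60)
  deg <- sprintf("g%02d", 1:8)
  e <- enrich(deg, db, background = universe)
  expect_equal(e$n[1], 8L)
  expect_equal(e$N[1], 60L)
  expect_equal(e$m[e$pathway_id == "hit"], 8L)
  expect_equal(e$m[e$pathway_id == "miss"], 0L)
  expect_equal(e$p_raw[e$pathway_id == "miss"], 1)
  expect_equal(e$m[e$pathway_id == "part"],
               length(intersect(deg, db$members$part)))
  expect_equal(e$pathway_id[1], "hit")     # smallest p first
  expect_true(all(diff(e$p_raw) >= 0))
  expect_equal(e$percent, 100 * e$m / e$n)
  expect_equal(e$p_adj, pmin(1, e$p_raw * nrow(e)))
  expect_error(enrich("absent", db, background = universe),
               "no annotatable DEGs")
})

test_that("a strongly planted pathway ranks first in its enrichment table", {
  ex <- generate_experiment(experiment_spec(
    n_genes = 2000L, library_sizes = c(control = 5e5, fast = 5e5, slow = 5e5),
    planted = c(shared_up = 80L), fold_change = 4, n_pathways = 50L,
    planted_enriched = list(list(pathway = 7L, class = "shared_up",
                                 factor = 10)),
    seed = 21))
  cf <- run_contrast(ex$counts, "control", "fast")
  e <- enrich(deg_ids(cf), ex$pathways)
  expect_equal(e$pathway_id[1], "pw007")
})

test_that("the four-type classification follows the significance pattern", {
  # fast-only significance -> III; both, later contrast more significant -> II
  expect_equal(as.character(
    classify_pathway_types(c(p = 0.004), c(p = 0.025), c(p = 0.061))$type),
    "III")
  expect_equal(as.character(
    classify_pathway_types(c(p = NA_real_), c(p = 0.002), c(p = 0.021))$type),
    "IV")
  expect_equal(as.character(
    classify_pathway_types(c(p = 0.013), c(p = 0.026), c(p = 5.53e-6))$type),
    "II")
  # slow-only -> I; nothing significant -> none
  expect_equal(as.character(
    classify_pathway_types(c(p = 0.2), c(p = 0.2), c(p = 0.01))$type), "I")
  expect_equal(as.character(
    classify_pathway_types(c(p = 0.2), c(p = 0.2), c(p = 0.51))$type),
    "none")
  # boundary: p equal to alpha is significant
  expect_equal(as.character(
    classify_pathway_types(c(p = 0.5), c(p = 0.5), c(p = 0.05))$type), "I")
  # present only in the fast/slow table -> none, not an error
  res <- classify_pathway_types(c(only_fs = 0.001),
                                c(other = 0.01), c(other = 0.005))
  expect_equal(as.character(res$type[res$pathway_id == "only_fs"]), "none")
  # the rate-difference rule is overridable
  res2 <- classify_pathway_types(c(p = 0.5), c(p = 0.01), c(p = 0.02),
                                 rate_difference = function(...) TRUE)
  expect_equal(as.character(res2$type), "II")
})

test_that("classification accepts enrichment tables directly", {
  db <- pathway_db(list(pw1 = sprintf("g%02d", 1:10),
                        pw2 = sprintf("g%02d", 11:40)))
  deg <- sprintf("g%02d", 1:9)
  e1 <- enrich(deg, db)
  e2 <- enrich(sprintf("g%02d", 30:40), db)
  res <- classify_pathway_types(e1, e1, e2)
  expect_setequal(res$pathway_id, c("pw1", "pw2"))
  expect_equal(res$p_fs[res$pathway_id == "pw1"],
               e1$p_raw[e1$pathway_id == "pw1"])
})
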