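small_spec <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 600, n_deg_a = 80, n_deg_b = 120,
         similarity_overlap = 0.1, retention_a = 0.9,
         retention_b = 0.7, novelty = 0.25, seed = 101),
    list(...))
  do.call(synthetic_spec, args)
}

test_that("the same spec regenerates identical tables", {
  e1 <- generate_experiment(small_spec())
  e2 <- generate_experiment(small_spec())
  for (nm in c("A", "B", "AB")) {
    expect_identical(tibble::as_tibble(e1$tables[[nm]]),
                     tibble::as_tibble(e2$tables[[nm]]))
  }
  expect_identical(e1$ground_truth, e2$ground_truth)

  # a different seed moves members but keeps the design sizes
  e3 <- generate_experiment(small_spec(seed = 202))
  expect_false(identical(e1$ground_truth$class, e3$ground_truth$class))
  expect_equal(table(e1$ground_truth$class)[c("A-only", "B-only", "shared")],
               table(e3$ground_truth$class)[c("A-only", "B-only", "shared")])
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(555)
  before <- .Random.seed
  generate_experiment(small_spec())
  expect_identical(.Random.seed, before)
})

test_that("thresholding the tables recovers the ground truth exactly", {
  exp <- generate_experiment(small_spec())
  gt <- exp$ground_truth
  degs_a <- call_degs(exp$tables$A)
  degs_b <- call_degs(exp$tables$B)
  degs_ab <- call_degs(exp$tables$AB)

  a_true <- gt$gene_id[gt$class %in% c("A-only", "shared")]
  b_true <- gt$gene_id[gt$class %in% c("B-only", "shared")]
  ab_true <- gt$gene_id[gt$retained_in_ab]
  expect_setequal(all_degs(degs_a), a_true)
  expect_setequal(all_degs(degs_b), b_true)
  expect_setequal(all_degs(degs_ab), ab_true)

  # directions carried by each gene are reproduced by the calls
  up_true <- gt$gene_id[gt$direction == "up"]
  expect_setequal(degs_a$up, intersect(a_true, up_true))
  expect_setequal(degs_ab$up, intersect(ab_true, up_true))

  # realised region counts match a fresh Venn of the true sets
  vp <- venn_partition(list(A = a_true, B = b_true, AB = ab_true))
  expect_equal(unname(venn_marginals(vp)$totals),
               unname(exp$region_counts$totals))
})

test_that("degenerate limits: full retention and zero novelty", {
  spec <- small_spec(retention_a = 1, retention_b = 1, novelty = 0)
  exp <- generate_experiment(spec)
  a <- call_degs(exp$tables$A); b <- call_degs(exp$tables$B)
  ab <- call_degs(exp$tables$AB)
  expect_setequal(all_degs(ab), union(all_degs(a), all_degs(b)))
  rep <- crosstalk_report(a, b, ab)
  expect_equal(rep$suppression, rep(0, 3))
  expect_equal(rep$novel_interaction, rep(0, 3))
})

test_that("novelty 0.5 is recovered within three binomial standard errors", {
  spec <- synthetic_spec(n_genes = 8000, n_deg_a = 800, n_deg_b = 800,
                         similarity_overlap = 0.1, retention_a = 0.9,
                         retention_b = 0.8, novelty = 0.5, seed = 7)
  exp <- generate_experiment(spec)
  rep <- crosstalk_report(call_degs(exp$tables$A), call_degs(exp$tables$B),
                          call_degs(exp$tables$AB))
  est <- rep$novel_interaction[rep$direction == "all"]
  moments <- expected_scores(spec)
  nov <- moments[moments$estimator == "novel_interaction", ]
  expect_lt(abs(est - 0.5), max(3 * nov$se, abs(nov$expectation - 0.5) +
                                  3 * nov$se))
  expect_lt(abs(est - nov$expectation), 3 * nov$se + 1e-9)
})

test_that("noisy boundary genes stay null by p but blur fold-changes", {
  spec <- small_spec(noisy_boundary = TRUE)
  exp <- generate_experiment(spec)
  gt <- exp$ground_truth
  called <- all_degs(call_degs(exp$tables$A))
  a_true <- gt$gene_id[gt$class %in% c("A-only", "shared")]
  # recovery still exact: borderline genes fail the p cutoff
  expect_setequal(called, a_true)
  null_fc <- abs(exp$tables$A$log2fc[exp$tables$A$gene_id %in%
                                       gt$gene_id[gt$class == "null"]])
  expect_gt(max(null_fc), spec$fc_threshold * 0.9)
})

test_that("infeasible specs are rejected with clear errors", {
  expect_error(synthetic_spec(n_genes = 100, n_deg_a = 80, n_deg_b = 80,
                              similarity_overlap = 0),
               "exceed the universe")
  expect_error(synthetic_spec(similarity_overlap = 1.2), "proportions")
  expect_error(synthetic_spec(novelty = 1), "novelty")
  expect_error(synthetic_spec(n_deg_a = 10, n_deg_b = 100,
                              similarity_overlap = 0.5),
               "shared genes exceed")
  # novelty demanding more genes than the null pool holds
  expect_error(
    generate_experiment(synthetic_spec(n_genes = 250, n_deg_a = 100,
                                       n_deg_b = 100,
                                       similarity_overlap = 0,
                                       novelty = 0.9)),
    "null pool")
})

test_that("a one-cell sweep matches generate + report run by hand", {
  grid <- data.frame(retention_b = 0.7)
  base <- small_spec()
  sw <- sweep_experiments(grid, replicates = 1, base = base)
  expect_equal(nrow(sw), 1)

  spec <- small_spec(retention_b = 0.7, seed = base$seed)
  exp <- generate_experiment(spec)
  rep <- crosstalk_report(call_degs(exp$tables$A), call_degs(exp$tables$B),
                          call_degs(exp$tables$AB))
  all_row <- rep[rep$direction == "all", ]
  expect_equal(sw$suppression, all_row$suppression)
  expect_equal(sw$novel_interaction, all_row$novel_interaction)
})

test_that("mean suppression falls as retention of B drops", {
  grid <- data.frame(retention_b = c(1.0, 0.8, 0.6))
  base <- synthetic_spec(n_genes = 2000, n_deg_a = 300, n_deg_b = 300,
                         similarity_overlap = 0, retention_a = 1.0,
                         novelty = 0.2, seed = 31)
  sw <- sweep_experiments(grid, replicates = 5, base = base)
  means <- tapply(sw$suppression, sw$retention_b, mean)
  means <- means[order(as.numeric(names(means)), decreasing = TRUE)]
  expect_true(all(diff(means) < 0))
  # with retention_a = 1 and no shared genes the expectation is r_B - 1
  expect_equal(unname(means[["1"]]), 0, tolerance = 0.05)
})
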