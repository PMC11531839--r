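test_that("venn_partition enumerates the hand-worked three-set example", {
  vp <- venn_partition(list(A = c("a", "b"), B = c("b", "c"),
                            AB = c("b", "c", "d")))
  expect_equal(region_members(vp, "A"), "a")
  expect_length(region_members(vp, "B"), 0)
  expect_equal(region_members(vp, "AB"), "d")
  expect_length(region_members(vp, "A&B"), 0)
  expect_length(region_members(vp, "A&AB"), 0)
  expect_equal(region_members(vp, "B&AB"), "c")
  expect_equal(region_members(vp, "A&B&AB"), "b")
  expect_equal(sum(vp$count), 4)  # |A ∪ B ∪ AB|
})

test_that("three identical sets put everything in the triple region", {
  g <- c("x", "y", "z")
  vp <- venn_partition(list(P = g, Q = g, R = g))
  expect_equal(region_count(vp, "P&Q&R"), 3L)
  expect_equal(sum(vp$count), 3)
})

test_that("venn_partition matches the brute-force membership tally", {
  withr::local_seed(42)
  for (i in 1:25) {
    sets <- random_set_triple(50)
    if (all(lengths(sets) == 0)) next
    vp <- venn_partition(sets)
    oracle <- brute_force_venn(sets)
    got <- setNames(vp$count, vp$region)
    expect_equal(got[names(oracle)], oracle)
    # marginal consistency: summed regions recover each set's cardinality
    marg <- venn_marginals(vp)
    expect_equal(unname(marg$totals), unname(lengths(lapply(sets, unique))))
  }
})

test_that("count-mode partition agrees with the set-mode partition", {
  withr::local_seed(99)
  for (i in 1:25) {
    sets <- random_set_triple(40)
    vp <- venn_partition(sets)
    marg <- venn_marginals(vp)
    from_counts <- venn3_from_counts(marg$totals, marg$pairwise, marg$triple,
                                     labels = names(sets))
    expect_equal(setNames(from_counts$count, from_counts$region),
                 setNames(as.integer(vp$count), vp$region))
  }
})

test_that("identical-set counts collapse into the triple region", {
  vp <- venn3_from_counts(c(5, 5, 5), pairwise = c(5, 5, 5), triple = 5)
  expect_equal(region_count(vp, "A&B&C"), 5L)
  expect_equal(sum(vp$count), 5L)
})

test_that("inconsistent summary counts are rejected", {
  expect_error(venn3_from_counts(c(10, 10, 10), pairwise = c(11, 0, 0),
                                 triple = 0),
               "negative")
  expect_error(venn3_from_counts(c(-1, 5, 5), pairwise = c(0, 0, 0),
                                 triple = 0),
               "non-negative")
})

test_that("directionality concordance counts shared-direction genes", {
  a <- deg_sets("A", up = c("g1", "g2"), down = "g3")
  b <- deg_sets("B", up = "g1", down = c("g2", "g3"))
  rep <- directionality_concordance(a, b)
  expect_equal(rep$n_common, 3)
  expect_equal(rep$n_same_direction, 2)
  expect_equal(rep$fraction_same, 2 / 3)

  # identity: every common gene agrees
  expect_equal(directionality_concordance(a, a)$fraction_same, 1)

  # symmetric in its arguments
  expect_equal(directionality_concordance(b, a)$fraction_same,
               rep$fraction_same)

  # no common genes -> undefined fraction, not zero
  c_set <- deg_sets("C", up = "zz")
  empty <- directionality_concordance(a, c_set)
  expect_equal(empty$n_common, 0)
  expect_true(is.na(empty$fraction_same))

  # restriction must stay inside the common genes
  expect_error(directionality_concordance(a, b, restrict_to = "zz"),
               "not common")
  restricted <- directionality_concordance(a, b, restrict_to = c("g1", "g2"))
  expect_equal(restricted$n_common, 2)
})

test_that("mean_amplitude reproduces direct recomputation", {
  tab1 <- as_de_table(data.frame(gene_id = c("a", "b"), log2fc = c(1, 3),
                                 adj_p = c(0.01, 0.01)), "t1")
  expect_equal(mean_amplitude(c("a", "b"), list(tab1))$mean_log2fc, 2)

  single <- mean_amplitude("a", list(tab1))
  expect_equal(single$mean_log2fc, 1)
  expect_equal(single$sd_log2fc, 0)

  withr::local_seed(5)
  genes <- sprintf("g%02d", 1:30)
  tabs <- lapply(c("x", "y", "z"), function(lab) {
    as_de_table(data.frame(gene_id = genes, log2fc = rnorm(30),
                           adj_p = runif(30)), lab)
  })
  names(tabs) <- c("x", "y", "z")
  pick <- sample(genes, 20)
  res <- mean_amplitude(pick, tabs)
  for (i in 1:3) {
    fc <- tabs[[i]]$log2fc[match(pick, tabs[[i]]$gene_id)]
    expect_equal(res$mean_log2fc[i], mean(fc))
    expect_equal(res$sd_log2fc[i], sd(fc))
  }

  expect_error(mean_amplitude("absent", list(tab1)), "absent")
})

test_that("omic concordance classifies quadrants and recovers correlation", {
  mrna <- as_de_table(data.frame(gene_id = c("g1", "g2", "g3"),
                                 log2fc = c(-1, 2, 0.5),
                                 adj_p = c(0.01, 0.01, 0.01)))
  prot <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(1, 3, -0.2))
  res <- omic_fc_concordance(mrna, prot)
  pg <- tidy(res)
  expect_equal(pg$quadrant[pg$gene_id == "g1"], "mrna_down_protein_up")
  expect_equal(pg$quadrant[pg$gene_id == "g2"], "both_up")
  expect_equal(pg$quadrant[pg$gene_id == "g3"], "mrna_up_protein_down")

  # identical paired vectors give rank correlation 1
  prot_same <- data.frame(gene_id = mrna$gene_id, log2fc = mrna$log2fc)
  expect_equal(omic_fc_concordance(mrna, prot_same)$spearman_rho, 1)

  # 50 simulated pairs: rho matches direct recomputation on matched pairs
  withr::local_seed(31)
  genes <- sprintf("g%02d", 1:50)
  m <- as_de_table(data.frame(gene_id = genes, log2fc = rnorm(50),
                              adj_p = runif(50)))
  p <- data.frame(gene_id = sample(genes), log2fc = rnorm(50))
  res2 <- omic_fc_concordance(m, p)
  manual <- cor(m$log2fc, p$log2fc[match(genes, p$gene_id)],
                method = "spearman")
  expect_equal(res2$spearman_rho, manual)

  expect_error(
    omic_fc_concordance(mrna, data.frame(gene_id = "zz", log2fc = 1)),
    "no shared gene")
})

test_that("qPCR relative expression follows 2^deltaCp", {
  cp <- data.frame(sample = c("s1", "s1", "s2", "s2"),
                   gene = c("REF", "GOI", "REF", "GOI"),
                   cp = c(20, 22, 20, 18))
  res <- relative_expression(cp, "REF")
  expect_equal(res$delta_cp, c(-2, 2))
  expect_equal(res$rel_expr, c(0.25, 4))
  expect_error(relative_expression(cp, "nope"), "reference gene not found")
})
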