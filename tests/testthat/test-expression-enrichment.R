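toy_expr <- function(values_a, values_b) {
  m <- cbind(a = values_a, b = values_b)
  rownames(m) <- sprintf("g%02d", seq_along(values_a))
  list(expr = m, conditions = data.frame(sample = c("a", "b"),
                                         condition = c("a", "b")))
}

test_that("log2 fold change uses a strict threshold boundary", {
  t <- toy_expr(c(10, 10, 8), c(20, 30, 8))
  de <- compute_log2fc(t$expr, t$conditions, "a", "b")
  expect_equal(de$log2fc, c(1, log2(3), 0))
  expect_equal(de$is_de, c(FALSE, TRUE, FALSE))  # exactly 1 is never DE
  expect_error(compute_log2fc(t$expr, t$conditions, "a", "missing"), "no samples")
})

test_that("DE intersection matches set algebra, with direction consistency", {
  mk <- function(genes, fcs) data.frame(gene = genes, log2fc = fcs,
                                        is_de = abs(fcs) > 1,
                                        stringsAsFactors = FALSE)
  a <- mk(c("g1", "g2", "g3", "g4"), c(2, -2, 1.5, 0.2))
  b <- mk(c("g1", "g2", "g3", "g5"), c(1.8, 2.2, -1.2, 3))
  expect_equal(intersect_de(a, b, direction_consistent = FALSE), c("g1", "g2", "g3"))
  expect_equal(intersect_de(a, b, direction_consistent = TRUE), "g1")
  expect_equal(intersect_de(a, a), c("g1", "g2", "g3"))
  expect_length(intersect_de(a[4, ], b), 0L)
  # randomized comparison against explicit set operations
  set.seed(7)
  for (i in 1:10) {
    fa <- mk(sprintf("g%02d", 1:20), rnorm(20, sd = 1.2))
    fb <- mk(sprintf("g%02d", 1:20), rnorm(20, sd = 1.2))
    want <- sort(intersect(fa$gene[fa$is_de], fb$gene[fb$is_de]))
    expect_equal(intersect_de(fa, fb, direction_consistent = FALSE), want)
  }
})

test_that("hypergeometric overlap p equals combinatorial enumeration", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(S = universe[1:6])
  de <- universe[c(1:4, 10:12)]  # overlap 4 of 6, draw 7 from 20
  out <- gene_set_overlap(de, sets, universe)
  expect_equal(out$overlap, 4L)
  expect_equal(out$p_hyper, enum_hyper_tail(4, 6, 20, 7), tolerance = 1e-12)
  # set fully inside the DE list: minimal tail for its size
  full <- gene_set_overlap(universe[1:7], list(S = universe[1:3]), universe)
  expect_equal(full$overlap, 3L)
  expect_equal(full$p_hyper, enum_hyper_tail(3, 3, 20, 7), tolerance = 1e-12)
  # empty intersection: p in the upper-tail = 1 region
  none <- gene_set_overlap(universe[15:17], list(S = universe[1:3]), universe)
  expect_equal(none$overlap, 0L)
  expect_equal(none$p_hyper, 1)
  expect_error(gene_set_overlap(de, list(S = sprintf("x%02d", 1:30)), universe),
               "larger than")
})

test_that("enrichment score reproduces hand-enumerated running sums", {
  prof <- rank_profile(c(a = 5, b = 4, c = 3, d = 2, e = 1))
  # |S| = 1 at rank 1: first step reaches the maximum of 1
  expect_equal(gsea_es(prof, "a", weight_p = 0), 1.0)
  # set at ranks {1, 3}: running sum (0.5, 1/6, 2/3, 1/3, 0)
  expect_equal(gsea_es(prof, c("a", "c"), weight_p = 0), 2 / 3, tolerance = 1e-12)
  # bounded in [-1, 1] on random inputs, and invariant under monotone
  # transformation of the statistic at weight 0
  set.seed(11)
  for (i in 1:20) {
    st <- setNames(rnorm(40), sprintf("g%02d", 1:40))
    pr <- rank_profile(st)
    s <- sample(names(st), 6)
    es <- gsea_es(pr, s, weight_p = 0)
    expect_gte(es, -1); expect_lte(es, 1)
    pr2 <- rank_profile(exp(st))  # monotone transform, same ranking
    expect_equal(gsea_es(pr2, s, weight_p = 0), es, tolerance = 1e-12)
  }
  expect_error(gsea_es(prof, "zz"), "does not intersect")
  expect_error(gsea_es(prof, prof$gene), "entire")
})

test_that("reversing the profile negates the score pattern at weight 0", {
  set.seed(13)
  st <- setNames(sort(rnorm(30), decreasing = TRUE), sprintf("g%02d", 1:30))
  prof <- rank_profile(st)
  rev_prof <- data.frame(gene = rev(prof$gene), stat = rev(prof$stat))
  for (i in 1:10) {
    s <- sample(prof$gene, 5)
    expect_equal(gsea_es(rev_prof, s, weight_p = 0),
                 -gsea_es(prof, s, weight_p = 0), tolerance = 1e-12)
  }
})

test_that("weighted enrichment score agrees with the fgsea reference", {
  skip_if_not_installed("fgsea")
  set.seed(17)
  for (i in 1:10) {
    st <- setNames(rnorm(60), sprintf("g%02d", 1:60))
    prof <- rank_profile(st)
    s <- sample(prof$gene, 9)
    ref <- fgsea::calcGseaStat(setNames(prof$stat, prof$gene),
                               which(prof$gene %in% s), gseaParam = 1)
    expect_equal(gsea_es(prof, s, weight_p = 1), ref, tolerance = 1e-10)
  }
})

test_that("permutation p respects the add-one bounds and recovers planted sets", {
  set.seed(19)
  st <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  prof <- rank_profile(st)
  r <- gsea_permutation_p(prof, sample(prof$gene, 10), n_perm = 50, seed = 1)
  expect_gte(r$p_perm, 1 / 51)
  expect_lte(r$p_perm, 1)
  # planted coherent shift in the noiseless limit: ES > 0.4 and significant
  planted <- sprintf("G%04d", 1:20)
  cfg <- expr_sim_config(n_genes = 400L, noise_sd = 0,
                         enriched_set = list(name = "S", genes = planted,
                                             condition = "mutant", shift = 2),
                         seed = 23)
  sim <- simulate_expression(cfg)
  de <- compute_log2fc(sim$expr, sim$conditions, "wild", "mutant")
  prof2 <- rank_profile(setNames(de$log2fc, de$gene))
  res <- gsea_permutation_p(prof2, planted, n_perm = 1000, seed = 3)
  expect_gt(res$es, 0.4)
  expect_lt(res$p_perm, 0.05)
  expect_true(res$significant)
  expect_error(gsea_permutation_p(prof, prof$gene), "smaller than")
})

test_that("fixed-direction permutation p-values are uniform under the null", {
  set.seed(42)
  stats <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  prof <- rank_profile(stats)
  ps <- vapply(1:200, function(i) {
    s <- sample(prof$gene, 10)
    gsea_permutation_p(prof, s, weight_p = 0, n_perm = 99, seed = i,
                       alternative = "greater")$p_perm
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
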