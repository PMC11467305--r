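test_that("frequency filter applies a strict threshold and a novel pathway", {
  v <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                  af_1kg_eas = c(0.02, NA, 0.01, 0.005),
                  af_esp = c(NA, NA, 0.001, 0.02),
                  af_esp6500 = NA_real_, stringsAsFactors = FALSE)
  res <- frequency_filter(v)
  # 0.02 removed; all-absent (novel) retained; 0.01 removed (strict <);
  # one field rare but another common -> removed
  expect_equal(res$verdict, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(res$reason[2], "novel_pass")
  # novel variants removed when treat_absent_as_pass is off
  res2 <- frequency_filter(v, frequency_rule(treat_absent_as_pass = FALSE))
  expect_false(res2$verdict[2])
  expect_error(frequency_filter(v, frequency_rule(databases = "af_nope")),
               "unknown AF field")
})

test_that("segregation filter matches exhaustive enumeration on random matrices", {
  for (seed in 1:8) {
    rp <- random_ped_and_gt(n_variants = 25, seed = seed)
    v <- data.frame(chrom = "1", pos = seq_len(25), ref = "A", alt = "G")
    rule <- segregation_rule(min_carriers = c(MPLC = 5L, NODULE = 8L))
    got <- segregation_filter(v, rp$gt, rp$ped, rule)$verdict
    want <- brute_force_segregation(rp$gt, rp$ped,
                                    min_carriers = c(MPLC = 5L, NODULE = 8L))
    expect_identical(unname(got), want)
  }
})

test_that("segregation handles the family pattern, control carriers and missing data", {
  fx <- build_family_fixture()
  v <- fx$annotations[1:3, ]
  gt <- fx$genotypes[1:3, , drop = FALSE]
  res <- segregation_filter(v, gt, fx$pedigree)
  expect_true(all(res$verdict))  # 5/5 MPLC + 8/9 nodule + 0 unaffected
  # a het in the unaffected member kills the variant
  gt2 <- gt; gt2[1, "UNAFFECTED_1"] <- 1L
  expect_false(segregation_filter(v, gt2, fx$pedigree)$verdict[1])
  # missing genotype in a required carrier counts as non-carrier (warned)
  gt3 <- gt; gt3[1, "MPLC_1"] <- NA_integer_
  expect_warning(res3 <- segregation_filter(v, gt3, fx$pedigree), "missing")
  expect_false(res3$verdict[1])
  # rule larger than the group size is a configuration error
  expect_error(segregation_filter(v, gt, fx$pedigree,
                                  segregation_rule(min_carriers = c(MPLC = 6L))),
               "only 5")
})

test_that("deleteriousness rule combines SIFT and PolyPhen as configured", {
  v <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                  sift_call = c("deleterious", "tolerated", NA, "deleterious"),
                  polyphen_call = c("benign", "probably_damaging", NA, "probably_damaging"),
                  stringsAsFactors = FALSE)
  either <- suppressMessages(deleteriousness_filter(v))
  expect_equal(either$verdict, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(either$n_unscored, 1L)
  both <- suppressMessages(deleteriousness_filter(v, deleteriousness_rule("both")))
  expect_equal(both$verdict, c(FALSE, FALSE, FALSE, TRUE))
  sift <- suppressMessages(deleteriousness_filter(v, deleteriousness_rule("sift_only")))
  expect_equal(sift$verdict, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("cascade is order-invariant and monotone under rule loosening", {
  fx <- build_family_fixture()
  res <- suppressMessages(run_snv_cascade(fx$annotations, fx$genotypes, fx$pedigree))
  # pure intersection: the final set equals the AND of the three verdicts
  expect_equal(nrow(res$candidates), sum(rowSums(res$verdicts) == 3L))
  # loosening the frequency rule can only grow the candidate set
  loose <- suppressMessages(run_snv_cascade(
    fx$annotations, fx$genotypes, fx$pedigree,
    rules = list(frequency = frequency_rule(max_af = 0.05))))
  expect_true(all(res$candidates$gene %in% loose$candidates$gene))
  expect_gte(nrow(loose$candidates), nrow(res$candidates))
  # empty input -> empty report
  empty <- run_snv_cascade(fx$annotations[0, ], fx$genotypes[0, , drop = FALSE],
                           fx$pedigree)
  expect_equal(nrow(empty$candidates), 0L)
})

test_that("planted variants are recovered whenever their pattern satisfies the rule", {
  rule <- segregation_rule(min_carriers = c(MPLC = 3L, NODULE = 5L))
  n_eligible <- 0L
  for (seed in 1:100) {
    sim <- simulate_pedigree(sim_config(background_variant_count = 15L, seed = seed))
    res <- suppressMessages(run_snv_cascade(
      sim$annotations, sim$genotypes, sim$pedigree,
      rules = list(segregation = rule)))
    # replay the rule on the truth data
    carriers <- sim$genotypes[1, ] >= 1
    truth_ok <-
      sum(carriers[members_of_class(sim$pedigree, "MPLC")]) >= 3 &&
      sum(carriers[members_of_class(sim$pedigree, "NODULE")]) >= 5 &&
      sum(carriers[members_of_class(sim$pedigree, "UNAFFECTED")]) == 0
    in_candidates <- "PLANT_1" %in% res$candidates$gene
    expect_identical(in_candidates, truth_ok)
    n_eligible <- n_eligible + truth_ok
  }
  expect_gt(n_eligible, 0L)  # the property was exercised, not vacuous
})

test_that("cohort frequency renders 3.7% for 6/162 with an exact interval", {
  cs <- carrier_frequency(6, 162)
  expect_equal(cs$percent, "3.7")
  expect_equal(cs$frequency, 6 / 162)
  # independent beta-quantile oracle for the Clopper-Pearson bounds
  expect_equal(unname(cs$ci95["low"]), qbeta(0.025, 6, 162 - 6 + 1), tolerance = 1e-12)
  expect_equal(unname(cs$ci95["high"]), qbeta(0.975, 6 + 1, 162 - 6), tolerance = 1e-12)
  zero <- carrier_frequency(0, 100)
  expect_equal(zero$percent, "0.0")
  expect_equal(unname(zero$ci95["low"]), 0)
  expect_error(carrier_frequency(5, 0), "n_total")
  expect_error(carrier_frequency(7, 6), "exceeds")
})

test_that("percentage rendering rounds half-up at one decimal", {
  expect_equal(carrier_frequency(1, 40)$percent, "2.5")
  expect_equal(carrier_frequency(9, 400)$percent, "2.3")  # 2.25 rounds up
})
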