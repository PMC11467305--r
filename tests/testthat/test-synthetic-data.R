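test_that("class counts are honored exactly and invalid configs are rejected", {
  sim <- simulate_pedigree(sim_config(seed = 11))
  expect_equal(pedigree_class_counts(sim$pedigree)[c("MPLC", "NODULE", "UNAFFECTED")],
               c(MPLC = 5L, NODULE = 9L, UNAFFECTED = 1L))
  expect_error(sim_config(n_members = 10, class_counts = c(MPLC = 5, NODULE = 9, UNAFFECTED = 1)),
               "sums to")
  expect_error(sim_config(penetrance = rbind(carrier = c(MPLC = 0.5, NODULE = 0.2),
                                             noncarrier = c(MPLC = 1, NODULE = 0))),
               "sum to 1")
})

test_that("degenerate penetrance makes phenotype equal carrier status", {
  identity_pen <- rbind(carrier = c(MPLC = 1, UNAFFECTED = 0),
                        noncarrier = c(MPLC = 0, UNAFFECTED = 1))
  cfg <- sim_config(n_members = 40L, class_counts = NULL, n_founders = 4L,
                    penetrance = identity_pen, background_variant_count = 0L,
                    seed = 5)
  sim <- simulate_pedigree(cfg)
  expect_identical(sim$pedigree$phenotype == "MPLC", unname(sim$carrier))
})

test_that("planted-allele transmission to offspring is Mendelian (~1/2)", {
  cfg <- sim_config(n_members = 1001L, class_counts = NULL, n_founders = 1L,
                    background_variant_count = 0L, seed = 21)
  sim <- simulate_pedigree(cfg)
  offspring <- sim$pedigree$id[!is.na(sim$pedigree$father_id)]
  expect_length(offspring, 1000L)
  frac <- mean(sim$genotypes[1, offspring] >= 1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
  # Mendelian consistency: every carrier child has a carrier father
  for (ch in offspring) {
    if (sim$genotypes[1, ch] >= 1) {
      fa <- sim$pedigree$father_id[sim$pedigree$id == ch]
      expect_gte(sim$genotypes[1, fa], 1)
    }
  }
})

test_that("background carrier fraction matches its annotated allele frequency", {
  cfg <- sim_config(n_members = 600L, class_counts = NULL, n_founders = 2L,
                    background_variant_count = 5L, seed = 31)
  sim <- simulate_pedigree(cfg)
  for (v in 2:6) {  # rows after the planted variant
    af <- sim$annotations$af_1kg_eas[v]
    skip_msg <- is.na(af)
    if (skip_msg) next  # novel variants carry no annotated AF to compare
    p_carrier <- 1 - (1 - af)^2
    frac <- mean(sim$genotypes[v, ] >= 1, na.rm = TRUE)
    expect_lt(abs(frac - p_carrier),
              3 * sqrt(p_carrier * (1 - p_carrier) / 600) + 1e-9)
  }
})

test_that("identical seed reproduces pedigree simulation bit for bit", {
  a <- simulate_pedigree(sim_config(seed = 9))
  b <- simulate_pedigree(sim_config(seed = 9))
  expect_identical(a, b)
  c <- simulate_pedigree(sim_config(seed = 10))
  expect_false(identical(a$genotypes, c$genotypes))
})

test_that("simulated SV tables honor planted per-group carrier counts", {
  ped <- simulate_pedigree(sim_config(seed = 2))$pedigree
  cfg <- sv_sim_config(
    n_background_events = 0L,
    planted_events = list(list(gene = "X", counts = c(MPLC = 5, NODULE = 9, UNAFFECTED = 0))),
    seed = 3)
  sv <- simulate_sv_table(cfg, ped)
  expect_equal(nrow(sv), 1L)
  counts <- recurrence_counts(sv, ped)
  expect_equal(counts[1, c("MPLC", "NODULE", "UNAFFECTED")],
               c(MPLC = 5L, NODULE = 9L, UNAFFECTED = 0L))
  expect_identical(sv, simulate_sv_table(cfg, ped))
  # over-subscribed class is a configuration error
  bad <- sv_sim_config(planted_events = list(list(gene = "Y", counts = c(UNAFFECTED = 2))))
  expect_error(simulate_sv_table(bad, ped), "carriers")
})

test_that("expression generator plants exact effects in the noiseless limit", {
  cfg <- expr_sim_config(
    n_genes = 50L, noise_sd = 0,
    de_effects = data.frame(gene = "G0007", condition = "mutant", log2_effect = 2.0),
    seed = 4)
  sim <- simulate_expression(cfg)
  de <- compute_log2fc(sim$expr, sim$conditions, "wild", "mutant")
  expect_equal(de$log2fc[de$gene == "G0007"], 2.0)
  expect_equal(de$log2fc[de$gene != "G0007"], rep(0, 49))
  expect_identical(sim$expr, simulate_expression(cfg)$expr)
  expect_error(
    expr_sim_config(de_effects = data.frame(gene = "G0001", condition = "nope",
                                            log2_effect = 1)),
    "unknown condition")
})

test_that("null DE count matches the Gaussian tail of the noise distribution", {
  sd <- 0.5
  cfg <- expr_sim_config(n_genes = 2000L, noise_sd = sd, seed = 12)
  sim <- simulate_expression(cfg)
  de <- compute_log2fc(sim$expr, sim$conditions, "wild", "mutant")
  # log2fc = difference of two independent N(0, sd^2) draws
  p_tail <- 2 * stats::pnorm(1, sd = sd * sqrt(2), lower.tail = FALSE)
  expect_lt(abs(sum(de$is_de) - 2000 * p_tail),
            3 * sqrt(2000 * p_tail * (1 - p_tail)))
})

test_that("limiting-dilution outcomes follow the single-hit dose response", {
  expect_equal(simulate_limiting_dilution(0, c(10, 100), 20, seed = 1)$n_positive,
               c(0L, 0L))
  sat <- simulate_limiting_dilution(1, c(1e6, 1e7), 20, seed = 1)
  expect_equal(sat$n_positive, sat$n_tested)
  big <- simulate_limiting_dilution(1e-4, 1e4, 10000, seed = 6)
  p <- 1 - exp(-1)
  expect_lt(abs(big$n_positive / 10000 - p), 3 * sqrt(p * (1 - p) / 10000))
  expect_error(simulate_limiting_dilution(1e-4, c(-5), 10), "positive")
})
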