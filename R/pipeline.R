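# Pipeline orchestration: run every stage end-to-end from a single config,
# with one seed fanning out deterministically to per-stage child seeds, and
# a demo() that materializes a complete, ready-to-run synthetic workspace.

#' Run the full prioritization pipeline
#'
#' Executes the toggled stages — SNV cascade, SV recurrence screen, cohort
#' carrier frequency, expression/enrichment, limiting-dilution and qPCR
#' models — from files on disk, writes per-stage TSV artifacts plus a YAML
#' summary into `config$out_dir`, and returns the summary. Identical
#' config and seed give identical outputs.
#'
#' @param config nested list (or path to a YAML file) with elements
#'   `inputs` (paths: `vcf`, `ped`, `annotations`, `sv_table`,
#'   `expression_a`, `expression_b`, `gmt`, `lda_a`, `lda_b`, `qpcr`),
#'   `stages` (logical toggles `snv`, `sv`, `cohort`, `expression`,
#'   `assays`), `cohort` (`n_carriers`, `n_total`), `expression`
#'   (`group_a`, `group_b`, `log2fc_min`, `es_min`, `n_perm`), `qpcr`
#'   (`control`), `seed`, and `out_dir`. [demo_workspace()] writes a complete
#'   example.
#' @return list of class `"pedscreen_run"` with one element per executed
#'   stage, invisibly. A stage failure halts the run with a stage-named
#'   error; artifacts of earlier stages are retained.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% list()
  on_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  summary <- list(seed = config$seed %||% NA_integer_)

  ped <- NULL
  if (isTRUE(stages$snv) || isTRUE(stages$sv)) {
    ped <- on_stage("pedigree", read_ped(config$inputs$ped))
    summary$pedigree <- as.list(pedigree_class_counts(ped))
  }

  if (isTRUE(stages$snv)) {
    summary$snv <- on_stage("snv", {
      vc <- read_vcf(config$inputs$vcf)
      ann <- read_annotations(config$inputs$annotations)
      variants <- join_annotations(vc$variants, ann)
      rules <- list(
        frequency = frequency_rule(max_af = config$snv$max_af %||% 0.01),
        segregation = segregation_rule(
          min_carriers = unlist(config$snv$min_carriers %||%
                                  list(MPLC = 5L, NODULE = 8L)),
          max_carriers_unaffected = config$snv$max_unaffected %||% 0L),
        deleteriousness = deleteriousness_rule(
          require = config$snv$deleterious %||% "either"))
      res <- run_snv_cascade(variants, vc$genotypes, ped, rules)
      write_candidate_report(res$candidates, file.path(out_dir, "snv_candidates.tsv"))
      list(n_candidates = nrow(res$candidates),
           stage_counts = as.list(res$stage_counts),
           top_variant = if (nrow(res$candidates)) res$candidates$gene[1] else NA,
           top_variant_carriers = if (nrow(res$candidates))
             res$candidates$carriers_total[1] else NA)
    })
  }

  if (isTRUE(stages$sv)) {
    summary$sv <- on_stage("sv", {
      sv <- read_sv_table(config$inputs$sv_table)
      rule <- recurrence_rule(
        min_rec = unlist(config$sv$min_rec %||% list(MPLC = 5L, NODULE = 9L)))
      scr <- screen_sv(sv, ped, rule)
      write_candidate_report(scr$retained, file.path(out_dir, "sv_candidates.tsv"))
      list(n_events = nrow(scr$retained),
           genes = scr$retained$gene, region_flags = scr$retained$region_flag)
    })
  }

  if (isTRUE(stages$cohort)) {
    summary$cohort <- on_stage("cohort", {
      cs <- carrier_frequency(config$cohort$n_carriers, config$cohort$n_total)
      list(n_carriers = cs$n_carriers, n_total = cs$n_total,
           percent = cs$percent, ci95 = as.list(cs$ci95))
    })
  }

  if (isTRUE(stages$expression)) {
    summary$expression <- on_stage("expression", {
      ex_cfg <- config$expression %||% list()
      ga <- ex_cfg$group_a %||% "wild"; gb <- ex_cfg$group_b %||% "mutant"
      thr <- ex_cfg$log2fc_min %||% 1
      run_line <- function(path) {
        m <- read_expression(path)
        conds <- data.frame(sample = colnames(m), condition = colnames(m),
                            stringsAsFactors = FALSE)
        compute_log2fc(m, conds, ga, gb, threshold = thr)
      }
      de_a <- run_line(config$inputs$expression_a)
      de_b <- run_line(config$inputs$expression_b)
      shared <- intersect_de(de_a, de_b)
      sets <- read_gmt(config$inputs$gmt)
      overlap <- gene_set_overlap(shared, sets, universe = de_a$gene)
      utils::write.table(overlap, file.path(out_dir, "set_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      prof <- rank_profile(stats::setNames(de_a$log2fc, de_a$gene))
      gsea_seed <- derive_seed(config$seed %||% 1L, "gsea")
      gsea <- lapply(names(sets), function(nm) {
        r <- gsea_permutation_p(prof, sets[[nm]],
                                n_perm = ex_cfg$n_perm %||% 1000L,
                                seed = gsea_seed,
                                es_min = ex_cfg$es_min %||% 0.4)
        data.frame(set = nm, es = r$es, p_perm = r$p_perm,
                   significant = r$significant, stringsAsFactors = FALSE)
      })
      gsea <- do.call(rbind, gsea)
      utils::write.table(gsea, file.path(out_dir, "gsea.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_de_a = sum(de_a$is_de), n_de_b = sum(de_b$is_de),
           n_shared_de = length(shared),
           significant_sets = gsea$set[gsea$significant])
    })
  }

  if (isTRUE(stages$assays)) {
    summary$assays <- on_stage("assays", {
      lda_a <- read_limiting_dilution(config$inputs$lda_a)
      lda_b <- read_limiting_dilution(config$inputs$lda_b)
      fit_a <- fit_single_hit(lda_a)
      fit_b <- fit_single_hit(lda_b)
      cmp <- compare_frequencies(lda_a, lda_b)
      q <- read_qpcr(config$inputs$qpcr)
      fold <- relative_expression(q, config$qpcr$control %||% "vector")
      utils::write.table(fold, file.path(out_dir, "qpcr_folds.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(f_hat_a = fit_a$f_hat, f_hat_b = fit_b$f_hat,
           lr_statistic = cmp$statistic, lr_p = cmp$p_value,
           qpcr_folds = stats::setNames(as.list(fold$fold), fold$condition))
    })
  }

  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  class(summary) <- "pedscreen_run"
  invisible(summary)
}

#' @method print pedscreen_run
#' @export
print.pedscreen_run <- function(x, ...) {
  cat("<pedscreen_run>\n")
  if (!is.null(x$snv)) cat(sprintf("  SNV candidates: %d (top: %s, %s/15 carriers)\n",
                                   x$snv$n_candidates, x$snv$top_variant,
                                   x$snv$top_variant_carriers))
  if (!is.null(x$sv)) cat(sprintf("  SV events: %d (%s)\n", x$sv$n_events,
                                  paste(x$sv$genes, collapse = ", ")))
  if (!is.null(x$cohort)) cat(sprintf("  cohort: %d/%d = %s%%\n",
                                      x$cohort$n_carriers, x$cohort$n_total,
                                      x$cohort$percent))
  if (!is.null(x$expression)) cat(sprintf("  shared DE genes: %d; significant sets: %s\n",
                                          x$expression$n_shared_de,
                                          paste(x$expression$significant_sets,
                                                collapse = ", ")))
  if (!is.null(x$assays)) cat(sprintf("  stem frequency: %.3g vs %.3g (LR p = %.3g)\n",
                                      x$assays$f_hat_a, x$assays$f_hat_b,
                                      x$assays$lr_p))
  invisible(x)
}

#' Materialize a ready-to-run demo workspace
#'
#' Writes the deterministic family fixture (VCF, PED, annotation and SV
#' tables) plus seeded synthetic expression matrices for two cell lines
#' with a planted differential/enriched gene set, limiting-dilution tables
#' for two groups with a genuine frequency difference, a qPCR Ct table,
#' the gene-set GMT, and a `config.yaml` that [run_all()] accepts as-is.
#' Repeated calls overwrite idempotently (the fixture part is bit-stable;
#' the synthetic part depends only on `seed`).
#'
#' @param dir workspace directory (created if needed).
#' @param seed integer master seed for the non-fixture synthetic data.
#' @return the config file path, invisibly.
#' @export
demo_workspace <- function(dir = tempfile("pedscreen_demo_"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- build_family_fixture()
  write_vcf(fx$annotations[c("chrom", "pos", "ref", "alt")], fx$genotypes,
            file.path(dir, "family.vcf"))
  write_ped(fx$pedigree, file.path(dir, "family.ped"))
  write_annotations(fx$annotations, file.path(dir, "annotations.tsv"))
  write_sv_table(fx$sv, file.path(dir, "sv_events.tsv"))

  stem_set <- sprintf("G%04d", 1:25)
  decoy_set <- sprintf("G%04d", 101:140)
  write_gmt(list(STEMNESS_UP = stem_set, DECOY_SET = decoy_set),
            file.path(dir, "sets.gmt"))
  de_truth <- data.frame(gene = sprintf("G%04d", 201:240),
                         condition = "mutant",
                         log2_effect = rep(c(2.5, -2.5), 20))
  for (line in c("a", "b")) {
    cfg <- expr_sim_config(
      n_genes = 600L, conditions = c("vector", "wild", "mutant"),
      de_effects = de_truth,
      enriched_set = list(name = "STEMNESS_UP", genes = stem_set,
                          condition = "mutant", shift = 2.5),
      noise_sd = 0.2,
      seed = derive_seed(seed, paste0("expr_", line)))
    sim <- simulate_expression(cfg)
    write_expression(sim$expr, file.path(dir, sprintf("expression_%s.tsv", line)))
  }

  lda_a <- simulate_limiting_dilution(1e-5, c(1e3, 1e4, 1e5), 10,
                                      seed = derive_seed(seed, "lda_a"), group = "wild")
  lda_b <- simulate_limiting_dilution(1e-4, c(1e3, 1e4, 1e5), 10,
                                      seed = derive_seed(seed, "lda_b"), group = "mutant")
  utils::write.csv(lda_a, file.path(dir, "lda_wild.csv"), row.names = FALSE)
  utils::write.csv(lda_b, file.path(dir, "lda_mutant.csv"), row.names = FALSE)

  qpcr <- with_seed(derive_seed(seed, "qpcr"), {
    conds <- rep(c("vector", "wild", "mutant"), each = 3)
    dct_true <- c(vector = 6, wild = 5, mutant = 3.5)
    data.frame(sample = paste0(conds, "_", rep(1:3, 3)), condition = conds,
               target_ct = 18 + dct_true[conds] + stats::rnorm(9, 0, 0.1),
               reference_ct = 18 + stats::rnorm(9, 0, 0.1),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(qpcr, file.path(dir, "qpcr.csv"), row.names = FALSE)

  config <- list(
    seed = as.integer(seed),
    out_dir = file.path(dir, "results"),
    stages = list(snv = TRUE, sv = TRUE, cohort = TRUE, expression = TRUE,
                  assays = TRUE),
    inputs = list(vcf = file.path(dir, "family.vcf"),
                  ped = file.path(dir, "family.ped"),
                  annotations = file.path(dir, "annotations.tsv"),
                  sv_table = file.path(dir, "sv_events.tsv"),
                  expression_a = file.path(dir, "expression_a.tsv"),
                  expression_b = file.path(dir, "expression_b.tsv"),
                  gmt = file.path(dir, "sets.gmt"),
                  lda_a = file.path(dir, "lda_wild.csv"),
                  lda_b = file.path(dir, "lda_mutant.csv"),
                  qpcr = file.path(dir, "qpcr.csv")),
    snv = list(max_af = 0.01, min_carriers = list(MPLC = 5L, NODULE = 8L),
               max_unaffected = 0L, deleterious = "either"),
    sv = list(min_rec = list(MPLC = 5L, NODULE = 9L)),
    cohort = list(n_carriers = 6L, n_total = 162L),
    expression = list(group_a = "wild", group_b = "mutant", log2fc_min = 1,
                      es_min = 0.4, n_perm = 1000L),
    qpcr = list(control = "vector")
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
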