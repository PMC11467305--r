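# Synthetic-data module: generates every input the pipeline consumes, with
# the statistical structure the analysis assumes (dominant transmission,
# rare/novel background variation, group-recurrent SV events, planted
# differential expression, single-hit dose response).

#' Configuration for pedigree + genotype simulation
#'
#' Describes a two-generation family: `n_founders` sibling founders (parents
#' ungenotyped) and `n_members - n_founders` children, each child assigned a
#' founder parent at random. Planted variants are heterozygous in every
#' founder and transmitted Mendelianly (probability 1/2 per child; the
#' married-in parent is assumed a non-carrier). Background variants are
#' independent per member at an allele frequency drawn from a Beta
#' distribution.
#'
#' Phenotypes are driven by carrier status of the first planted variant
#' through `penetrance`, a 2 x 4 matrix (rows `carrier`, `noncarrier`;
#' columns the phenotype classes) whose rows sum to 1. With
#' `class_counts = NULL` phenotypes are drawn independently from the
#' relevant penetrance row; with explicit counts the generator samples an
#' assignment conditioned on exactly those per-class totals, weighting each
#' member by its penetrance row (sequential weighted sampling without
#' replacement).
#'
#' @param n_members total pedigree size.
#' @param class_counts named integer vector over phenotype classes summing
#'   to `n_members`, or `NULL` for unconstrained penetrance draws.
#' @param n_founders number of founder siblings (all planted-variant
#'   carriers).
#' @param planted_variant_count number of planted heterozygous variants.
#' @param background_variant_count number of background variants.
#' @param background_af shape parameters `c(shape1, shape2)` of the Beta
#'   allele-frequency distribution for background variants.
#' @param novel_fraction probability that a background variant carries no
#'   population-frequency annotation at all (a "novel" variant).
#' @param penetrance 2 x 4 probability matrix, see Details.
#' @param genotype_missing_rate per-entry genotype missingness probability.
#' @param seed integer seed; all randomness in [simulate_pedigree()] flows
#'   from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_members = 15L,
                       class_counts = c(MPLC = 5L, NODULE = 9L, UNAFFECTED = 1L),
                       n_founders = 5L,
                       planted_variant_count = 1L,
                       background_variant_count = 100L,
                       background_af = c(shape1 = 0.5, shape2 = 10),
                       novel_fraction = 0.1,
                       penetrance = default_penetrance(),
                       genotype_missing_rate = 0,
                       seed = 1L) {
  if (!is_count(n_members) || n_members < 1) stopf("n_members must be a positive count")
  if (!is_count(n_founders) || n_founders < 1 || n_founders > n_members) {
    stopf("n_founders must be in [1, n_members]")
  }
  if (!is.null(class_counts)) {
    if (is.null(names(class_counts)) || !all(names(class_counts) %in% PHENO_CLASSES)) {
      stopf("class_counts must be named with phenotype classes")
    }
    if (sum(class_counts) != n_members) {
      stopf("class_counts sums to %d but n_members is %d", sum(class_counts), n_members)
    }
  }
  penetrance <- validate_penetrance(penetrance)
  if (!is_prob(genotype_missing_rate) || !is_prob(novel_fraction)) {
    stopf("rates must be probabilities in [0, 1]")
  }
  if (length(background_af) != 2L || any(background_af <= 0)) {
    stopf("background_af must be two positive Beta shape parameters")
  }
  structure(list(
    n_members = as.integer(n_members), class_counts = class_counts,
    n_founders = as.integer(n_founders),
    planted_variant_count = as.integer(planted_variant_count),
    background_variant_count = as.integer(background_variant_count),
    background_af = background_af, novel_fraction = novel_fraction,
    penetrance = penetrance, genotype_missing_rate = genotype_missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default penetrance matrix for the dominant model
#'
#' Carriers develop cancer (MPLC) with probability 0.35, nodules with 0.55
#' and stay unaffected with 0.10; non-carriers are unaffected with
#' probability 0.95. These defaults qualitatively reproduce a family where
#' 13 of 15 members carry the variant and a single non-carrier shows
#' nodules.
#' @return 2 x 4 probability matrix with rows `carrier`, `noncarrier`.
#' @export
default_penetrance <- function() {
  m <- rbind(
    carrier    = c(MPLC = 0.35, NODULE = 0.55, UNAFFECTED = 0.10, UNKNOWN = 0),
    noncarrier = c(MPLC = 0.01, NODULE = 0.04, UNAFFECTED = 0.95, UNKNOWN = 0)
  )
  m
}

validate_penetrance <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) != 2L) stopf("penetrance must have rows 'carrier' and 'noncarrier'")
  if (is.null(colnames(p))) stopf("penetrance columns must be named phenotype classes")
  miss <- setdiff(colnames(p), PHENO_CLASSES)
  if (length(miss)) stopf("unknown penetrance class(es): %s", paste(miss, collapse = ", "))
  full <- matrix(0, 2, length(PHENO_CLASSES),
                 dimnames = list(c("carrier", "noncarrier"), PHENO_CLASSES))
  full[, colnames(p)] <- p
  if (!is_prob(full)) stopf("penetrance entries must be probabilities")
  if (any(abs(rowSums(full) - 1) > 1e-8)) stopf("penetrance rows must sum to 1")
  full
}

# Sample one phenotype assignment with exact per-class totals, each member
# weighted by its penetrance row. Members are visited in random order;
# classes with exhausted quota get weight zero.
assign_phenotypes_conditional <- function(weights, class_counts) {
  n <- nrow(weights)
  remaining <- stats::setNames(integer(length(PHENO_CLASSES)), PHENO_CLASSES)
  remaining[names(class_counts)] <- as.integer(class_counts)
  out <- character(n)
  for (i in sample.int(n)) {
    w <- weights[i, ] * (remaining > 0)
    if (sum(w) == 0) {
      # penetrance row gives zero mass to every class with quota left
      w <- as.numeric(remaining > 0)
      if (sum(w) == 0) stopf("class_counts exhausted before all members assigned")
    }
    cls <- sample(PHENO_CLASSES, 1L, prob = w)
    out[i] <- cls
    remaining[cls] <- remaining[cls] - 1L
  }
  out
}

#' Simulate a dominant-transmission pedigree with genotypes and annotations
#'
#' @param config a [sim_config()].
#' @return A list with elements `pedigree` (a [pedigree()]), `genotypes`
#'   (integer matrix, variants x members, alt-allele counts with `NA` for
#'   missing) and `annotations` (data.frame of per-variant population
#'   frequencies, SIFT/PolyPhen calls and region class). Planted variants
#'   come first, named `PLANT_*`; the element `carrier` records the true
#'   carrier status (of the first planted variant) used for phenotype
#'   assignment.
#' @examples
#' sim <- simulate_pedigree(sim_config(seed = 7))
#' pedigree_class_counts(sim$pedigree)
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_members
    nf <- config$n_founders
    ids <- sprintf("M%02d", seq_len(n))
    father <- rep(NA_character_, n)
    if (n > nf) {
      father[(nf + 1L):n] <- ids[sample.int(nf, n - nf, replace = TRUE)]
    }
    sex <- sample(1:2, n, replace = TRUE)

    npl <- config$planted_variant_count
    nbg <- config$background_variant_count

    # planted genotypes: founders het; children inherit with p = 1/2
    gt_pl <- matrix(0L, nrow = npl, ncol = n)
    if (npl > 0) {
      gt_pl[, seq_len(nf)] <- 1L
      if (n > nf) {
        for (j in (nf + 1L):n) {
          gt_pl[, j] <- stats::rbinom(npl, 1L, 0.5)
        }
      }
    }

    carrier <- if (npl > 0) gt_pl[1L, ] >= 1L else rep(FALSE, n)
    weights <- config$penetrance[ifelse(carrier, "carrier", "noncarrier"), , drop = FALSE]
    phenotype <- if (is.null(config$class_counts)) {
      vapply(seq_len(n), function(i) sample(PHENO_CLASSES, 1L, prob = weights[i, ]),
             character(1))
    } else {
      assign_phenotypes_conditional(weights, config$class_counts)
    }

    ped <- pedigree(id = ids, father_id = father, mother_id = NA_character_,
                    sex = sex, phenotype = phenotype)

    # background variants: independent carriers at a Beta-distributed AF
    af_bg <- stats::rbeta(nbg, config$background_af[[1]], config$background_af[[2]])
    gt_bg <- matrix(stats::rbinom(nbg * n, 2L, rep(af_bg, n)), nrow = nbg, ncol = n)

    gt <- rbind(gt_pl, gt_bg)
    storage.mode(gt) <- "integer"

    ann <- rbind(
      planted_annotations(npl),
      background_annotations(nbg, af_bg, config$novel_fraction)
    )
    rownames(gt) <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
    colnames(gt) <- ids

    if (config$genotype_missing_rate > 0) {
      drop <- stats::runif(length(gt)) < config$genotype_missing_rate
      gt[drop] <- NA_integer_
    }

    list(pedigree = ped, genotypes = gt, annotations = ann,
         carrier = stats::setNames(carrier, ids))
  })
}

planted_annotations <- function(npl) {
  if (npl == 0) return(empty_annotations())
  data.frame(
    chrom = "17", pos = 41000000L + 100000L * seq_len(npl),
    ref = "C", alt = "T", gene = sprintf("PLANT_%d", seq_len(npl)),
    af_1kg_eas = 0.001, af_esp = 0.001, af_esp6500 = 0.002,
    sift_call = "deleterious", polyphen_call = "probably_damaging",
    region_class = "exonic", stringsAsFactors = FALSE
  )
}

background_annotations <- function(nbg, af_bg, novel_fraction) {
  if (nbg == 0) return(empty_annotations())
  sift <- sample(c("deleterious", "tolerated"), nbg, replace = TRUE, prob = c(0.3, 0.7))
  poly <- sample(c("probably_damaging", "possibly_damaging", "benign"), nbg,
                 replace = TRUE, prob = c(0.15, 0.15, 0.7))
  novel <- stats::runif(nbg) < novel_fraction
  ann <- data.frame(
    chrom = as.character(sample(1:22, nbg, replace = TRUE)),
    pos = sample.int(2e8L, nbg), ref = "A", alt = "G",
    gene = sprintf("BG_%04d", seq_len(nbg)),
    af_1kg_eas = af_bg, af_esp = af_bg, af_esp6500 = af_bg,
    sift_call = sift, polyphen_call = poly,
    region_class = sample(c("exonic", "non_exonic"), nbg, replace = TRUE),
    stringsAsFactors = FALSE
  )
  ann$af_1kg_eas[novel] <- NA_real_
  ann$af_esp[novel] <- NA_real_
  ann$af_esp6500[novel] <- NA_real_
  ann
}

empty_annotations <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene = character(), af_1kg_eas = numeric(),
             af_esp = numeric(), af_esp6500 = numeric(), sift_call = character(),
             polyphen_call = character(), region_class = character(),
             stringsAsFactors = FALSE)
}

#' Configuration for structural-variant table simulation
#'
#' @param n_background_events number of unconstrained random background
#'   events.
#' @param planted_events list of specifications, each a list with elements
#'   `gene`, `counts` (named carriers per phenotype class), and optionally
#'   `region_class` (default `"non_exonic"`) and `type`.
#' @param background_presence_prob per-member presence probability of a
#'   background event.
#' @param seed integer seed.
#' @return A list of class `"sv_sim_config"`.
#' @export
sv_sim_config <- function(n_background_events = 20L, planted_events = list(),
                          background_presence_prob = 0.2, seed = 1L) {
  if (!is_count(n_background_events)) stopf("n_background_events must be a count")
  structure(list(n_background_events = as.integer(n_background_events),
                 planted_events = planted_events,
                 background_presence_prob = background_presence_prob,
                 seed = as.integer(seed)),
            class = "sv_sim_config")
}

#' Simulate a structural-variant event table over a pedigree
#'
#' Each event row records its type (amplification, deletion, inversion,
#' translocation), breakpoints, gene and region annotation, and one 0/1
#' presence flag per pedigree member. Planted events are present in exactly
#' the configured number of members per phenotype class (members chosen at
#' random within the class); background events are present independently
#' per member.
#'
#' @param config a [sv_sim_config()].
#' @param ped a [pedigree()].
#' @return data.frame of class `"sv_table"`: columns `id`, `type`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `gene`, `region_class`, then one 0/1 column
#'   per member id.
#' @export
simulate_sv_table <- function(config, ped) {
  stopifnot(inherits(config, "sv_sim_config"))
  ped <- validate_pedigree(ped)
  with_seed(config$seed, {
    rows <- list()
    for (k in seq_along(config$planted_events)) {
      ev <- config$planted_events[[k]]
      counts <- ev$counts
      present <- stats::setNames(integer(nrow(ped)), ped$id)
      for (cls in names(counts)) {
        pool <- members_of_class(ped, cls)
        if (counts[[cls]] > length(pool)) {
          stopf("planted event '%s' wants %d carriers in class %s but the class has %d members",
                ev$gene, counts[[cls]], cls, length(pool))
        }
        present[sample(pool, counts[[cls]])] <- 1L
      }
      rows[[length(rows) + 1L]] <- sv_event_row(
        id = sprintf("SV_PLANT_%d", k),
        type = ev$type %||% "deletion",
        gene = ev$gene, region_class = ev$region_class %||% "non_exonic",
        present = present, pos_seed = 1000L * k
      )
    }
    for (k in seq_len(config$n_background_events)) {
      present <- stats::setNames(
        as.integer(stats::runif(nrow(ped)) < config$background_presence_prob), ped$id)
      rows[[length(rows) + 1L]] <- sv_event_row(
        id = sprintf("SV_BG_%03d", k),
        type = sample(SV_TYPES, 1L),
        gene = sprintf("SVBG_%03d", k),
        region_class = sample(c("exonic", "non_exonic"), 1L),
        present = present, pos_seed = 50000L + 1000L * k
      )
    }
    sv <- do.call(rbind, rows)
    if (is.null(sv)) sv <- sv_event_row(id = character(0))[0, ]
    rownames(sv) <- NULL
    class(sv) <- c("sv_table", "data.frame")
    sv
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sv_event_row <- function(id, type = "deletion", gene = NA_character_,
                         region_class = "non_exonic",
                         present = stats::setNames(integer(0), character(0)),
                         pos_seed = 0L) {
  base <- data.frame(id = id, type = type,
                     chrom1 = "2", pos1 = 1e6L + pos_seed,
                     chrom2 = "2", pos2 = 1e6L + pos_seed + 5000L,
                     gene = gene, region_class = region_class,
                     stringsAsFactors = FALSE)
  cbind(base, as.data.frame(as.list(present), optional = TRUE))
}

#' Configuration for expression-matrix simulation
#'
#' The generator works on the log2 scale: expression of gene g in sample s
#' is `baseline_g + effect(g, condition(s)) + N(0, noise_sd)`, then
#' exponentiated to the linear scale on which fold changes are computed.
#'
#' @param n_genes gene universe size.
#' @param conditions ordered condition labels (e.g.
#'   `c("vector", "wild", "mutant")`).
#' @param n_replicates samples per condition.
#' @param de_effects data.frame with columns `gene`, `condition`,
#'   `log2_effect`: additive log2 shifts planted in specific genes under
#'   specific conditions.
#' @param enriched_set optional list with `name`, `genes`, `condition`,
#'   `shift`: a coherent log2 shift planted in a whole gene set under one
#'   condition (makes the set enrichable in a ranked profile).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale
#'   (must be >= 0; 0 gives the noiseless limit).
#' @param seed integer seed.
#' @return list of class `"expr_sim_config"`.
#' @export
expr_sim_config <- function(n_genes = 1000L,
                            conditions = c("vector", "wild", "mutant"),
                            n_replicates = 1L,
                            de_effects = NULL,
                            enriched_set = NULL,
                            noise_sd = 0.25,
                            seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) stopf("n_genes must be a positive count")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.null(de_effects)) {
    stopifnot(all(c("gene", "condition", "log2_effect") %in% names(de_effects)))
    bad <- setdiff(de_effects$condition, conditions)
    if (length(bad)) stopf("de_effects references unknown condition(s): %s",
                           paste(unique(bad), collapse = ", "))
  }
  if (!is.null(enriched_set)) {
    stopifnot(all(c("name", "genes", "condition", "shift") %in% names(enriched_set)))
    if (!enriched_set$condition %in% conditions) {
      stopf("enriched_set references unknown condition '%s'", enriched_set$condition)
    }
  }
  structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 de_effects = de_effects, enriched_set = enriched_set,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "expr_sim_config")
}

#' Simulate a linear-scale expression matrix with planted effects
#'
#' @param config an [expr_sim_config()].
#' @return list with `expr` (numeric matrix genes x samples, linear scale),
#'   `conditions` (data.frame mapping sample to condition), and the truth
#'   records `de_effects` / `enriched_set` carried over from the config.
#'   Planted genes named in `de_effects` must exist in the gene universe
#'   `G0001...`; unknown genes are an error.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  for (g in unique(c(config$de_effects$gene, config$enriched_set$genes))) {
    if (!g %in% genes) stopf("planted gene '%s' is outside the gene universe", g)
  }
  with_seed(config$seed, {
    samples <- as.vector(t(outer(config$conditions, seq_len(config$n_replicates),
                                 function(a, b) paste0(a, "_r", b))))
    if (config$n_replicates == 1L) samples <- config$conditions
    cond_of <- rep(config$conditions, each = config$n_replicates)
    baseline <- stats::runif(config$n_genes, 4, 10)
    logex <- matrix(baseline, nrow = config$n_genes, ncol = length(samples),
                    dimnames = list(genes, samples))
    if (!is.null(config$de_effects)) {
      for (k in seq_len(nrow(config$de_effects))) {
        g <- config$de_effects$gene[k]
        cols <- which(cond_of == config$de_effects$condition[k])
        logex[g, cols] <- logex[g, cols] + config$de_effects$log2_effect[k]
      }
    }
    if (!is.null(config$enriched_set)) {
      cols <- which(cond_of == config$enriched_set$condition)
      logex[config$enriched_set$genes, cols] <-
        logex[config$enriched_set$genes, cols] + config$enriched_set$shift
    }
    if (config$noise_sd > 0) {
      logex <- logex + matrix(stats::rnorm(length(logex), 0, config$noise_sd),
                              nrow = nrow(logex))
    }
    list(expr = 2^logex,
         conditions = data.frame(sample = samples, condition = cond_of,
                                 stringsAsFactors = FALSE),
         de_effects = config$de_effects, enriched_set = config$enriched_set)
  })
}

#' Simulate a limiting-dilution outcome table under the single-hit model
#'
#' Each animal implanted with `d` cells becomes tumor-positive with
#' probability `1 - exp(-f_true * d)`, independently.
#'
#' @param f_true true active-cell frequency per cell (>= 0).
#' @param doses vector of positive cell doses.
#' @param n_per_dose animals tested per dose (recycled over doses).
#' @param seed integer seed.
#' @param group group label stored on the table.
#' @return data.frame with columns `group`, `dose`, `n_tested`,
#'   `n_positive`.
#' @examples
#' simulate_limiting_dilution(1e-4, c(1e3, 1e4, 1e5), 10, seed = 1)
#' @export
simulate_limiting_dilution <- function(f_true, doses, n_per_dose, seed = 1L,
                                       group = "sim") {
  if (!is.numeric(f_true) || length(f_true) != 1L || f_true < 0) {
    stopf("f_true must be a single frequency >= 0")
  }
  if (any(doses <= 0)) stopf("doses must be positive")
  n_per_dose <- rep_len(as.integer(n_per_dose), length(doses))
  with_seed(seed, {
    p <- 1 - exp(-f_true * doses)
    data.frame(group = group, dose = doses, n_tested = n_per_dose,
               n_positive = stats::rbinom(length(doses), n_per_dose, p),
               stringsAsFactors = FALSE)
  })
}
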