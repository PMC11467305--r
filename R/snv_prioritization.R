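# SNV candidate cascade: population frequency -> pedigree co-segregation ->
# predicted deleteriousness, plus the validation-cohort carrier-frequency
# statistic. The cascade is set-based filtering under a dominant model, not
# hypothesis testing; no multiple-testing correction applies.

#' Population-frequency rule
#'
#' A variant passes when every *present* allele-frequency field among
#' `databases` is strictly below `max_af`. Variants with all frequency
#' fields absent are "novel" and pass when `treat_absent_as_pass` is TRUE
#' (the default): absence of a database record is not evidence of
#' commonness.
#'
#' @param max_af exclusive upper bound on population allele frequency
#'   (default 0.01, i.e. "present in less than 1%").
#' @param databases annotation column names holding allele frequencies.
#' @param treat_absent_as_pass keep variants with no frequency record.
#' @return list of class `"frequency_rule"`.
#' @export
frequency_rule <- function(max_af = 0.01,
                           databases = c("af_1kg_eas", "af_esp", "af_esp6500"),
                           treat_absent_as_pass = TRUE) {
  if (!is.numeric(max_af) || max_af <= 0 || max_af > 1) stopf("max_af must be in (0, 1]")
  structure(list(max_af = max_af, databases = databases,
                 treat_absent_as_pass = isTRUE(treat_absent_as_pass)),
            class = "frequency_rule")
}

#' Co-segregation rule for a dominant model
#'
#' A variant passes when, in each phenotype class named in `min_carriers`,
#' at least that many members carry the variant (alt-allele count >= 1) and
#' at most `max_carriers_unaffected` UNAFFECTED members carry it.
#' UNKNOWN-class members are ignored. The nodule-class default of 8 (out of
#' 9) encodes tolerance for one non-penetrant-class member rather than a
#' hard-coded family pattern.
#'
#' @param min_carriers named minimum carrier counts per phenotype class.
#' @param max_carriers_unaffected maximum carriers allowed among UNAFFECTED
#'   members (default 0).
#' @param missing_policy how to treat missing genotypes:
#'   `"count_as_noncarrier"` (default, conservative for a presence
#'   requirement) or `"exclude_member"` (the member drops out of that
#'   variant's tally entirely).
#' @return list of class `"segregation_rule"`.
#' @export
segregation_rule <- function(min_carriers = c(MPLC = 5L, NODULE = 8L),
                             max_carriers_unaffected = 0L,
                             missing_policy = c("count_as_noncarrier", "exclude_member")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(names(min_carriers)) || !all(names(min_carriers) %in% PHENO_CLASSES)) {
    stopf("min_carriers must be named with phenotype classes")
  }
  if (!is_count(max_carriers_unaffected)) stopf("max_carriers_unaffected must be a count >= 0")
  structure(list(min_carriers = min_carriers,
                 max_carriers_unaffected = as.integer(max_carriers_unaffected),
                 missing_policy = missing_policy),
            class = "segregation_rule")
}

#' Deleteriousness rule over SIFT / PolyPhen calls
#'
#' @param require `"either"` (default), `"both"`, `"sift_only"` or
#'   `"polyphen_only"`: how the two predictors combine. Variants with both
#'   calls absent never pass and are counted in the stage log.
#' @param damaging_polyphen_levels PolyPhen categories counted as damaging.
#' @return list of class `"deleteriousness_rule"`.
#' @export
deleteriousness_rule <- function(require = c("either", "both", "sift_only", "polyphen_only"),
                                 damaging_polyphen_levels = c("probably_damaging",
                                                              "possibly_damaging")) {
  require <- match.arg(require)
  if (require %in% c("either", "both", "polyphen_only") &&
      length(damaging_polyphen_levels) == 0L) {
    stopf("damaging_polyphen_levels must be non-empty when PolyPhen is used")
  }
  structure(list(require = require,
                 damaging_polyphen_levels = damaging_polyphen_levels),
            class = "deleteriousness_rule")
}

#' Apply the population-frequency filter
#'
#' @param variants annotated variant data.frame (see [join_annotations()]).
#' @param rule a [frequency_rule()].
#' @return list with `retained` (subset of `variants`), `verdict` (logical
#'   per input variant) and `reason` (per-variant character trail).
#' @export
frequency_filter <- function(variants, rule = frequency_rule()) {
  stopifnot(inherits(rule, "frequency_rule"))
  miss <- setdiff(rule$databases, names(variants))
  if (length(miss)) stopf("unknown AF field(s): %s", paste(miss, collapse = ", "))
  af <- as.matrix(variants[, rule$databases, drop = FALSE])
  n_present <- rowSums(!is.na(af))
  all_rare <- rowSums(!is.na(af) & af >= rule$max_af) == 0L
  verdict <- ifelse(n_present == 0L, rule$treat_absent_as_pass, all_rare)
  reason <- ifelse(n_present == 0L,
                   ifelse(verdict, "novel_pass", "novel_fail"),
                   ifelse(verdict, sprintf("af_below_%g", rule$max_af), "af_too_common"))
  list(retained = variants[verdict, , drop = FALSE], verdict = verdict, reason = reason)
}

# Carrier counts per phenotype class for every variant row.
carrier_counts_by_class <- function(genotypes, ped,
                                    missing_policy = "count_as_noncarrier") {
  if (nrow(genotypes) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = length(PHENO_CLASSES),
                  dimnames = list(NULL, PHENO_CLASSES)))
  }
  counts <- sapply(PHENO_CLASSES, function(cls) {
    cols <- match(members_of_class(ped, cls), colnames(genotypes))
    if (length(cols) == 0L) return(rep(0L, nrow(genotypes)))
    g <- genotypes[, cols, drop = FALSE]
    rowSums(g >= 1L, na.rm = TRUE)
  })
  counts <- matrix(as.integer(counts), nrow = nrow(genotypes),
                   dimnames = list(rownames(genotypes), PHENO_CLASSES))
  counts
}

# Effective per-class group size per variant (accounts for exclude_member).
class_sizes_by_variant <- function(genotypes, ped, missing_policy) {
  sizes <- sapply(PHENO_CLASSES, function(cls) {
    cols <- match(members_of_class(ped, cls), colnames(genotypes))
    if (length(cols) == 0L) return(rep(0L, nrow(genotypes)))
    if (missing_policy == "exclude_member") {
      rowSums(!is.na(genotypes[, cols, drop = FALSE]))
    } else {
      rep(length(cols), nrow(genotypes))
    }
  })
  matrix(as.integer(sizes), nrow = nrow(genotypes),
         dimnames = list(rownames(genotypes), PHENO_CLASSES))
}

#' Apply the pedigree co-segregation filter
#'
#' @param variants variant data.frame (rows aligned with `genotypes`).
#' @param genotypes integer matrix of alt-allele counts (variants x
#'   members); `NA` means missing, handled per the rule's missing policy.
#' @param ped a [pedigree()]; members must match the matrix columns.
#' @param rule a [segregation_rule()].
#' @return list with `retained`, `verdict`, and `carrier_counts` (matrix of
#'   per-class carrier counts per input variant).
#' @export
segregation_filter <- function(variants, genotypes, ped, rule = segregation_rule()) {
  stopifnot(inherits(rule, "segregation_rule"))
  ped <- validate_pedigree(ped)
  if (!setequal(colnames(genotypes), ped$id)) {
    stopf("genotype matrix members do not match the pedigree")
  }
  if (nrow(variants) != nrow(genotypes)) stopf("variants and genotype rows differ")
  if (anyNA(genotypes) && rule$missing_policy == "count_as_noncarrier") {
    warnf("missing genotypes counted as non-carriers (%d entries)", sum(is.na(genotypes)))
  }
  cc <- pedigree_class_counts(ped)
  for (cls in names(rule$min_carriers)) {
    if (rule$min_carriers[[cls]] > cc[[cls]]) {
      stopf("rule demands %d carriers in class %s but the pedigree has only %d members",
            rule$min_carriers[[cls]], cls, cc[[cls]])
    }
  }
  counts <- carrier_counts_by_class(genotypes, ped, rule$missing_policy)
  verdict <- rep(TRUE, nrow(genotypes))
  for (cls in names(rule$min_carriers)) {
    verdict <- verdict & counts[, cls] >= rule$min_carriers[[cls]]
  }
  verdict <- verdict & counts[, "UNAFFECTED"] <= rule$max_carriers_unaffected
  list(retained = variants[verdict, , drop = FALSE], verdict = verdict,
       carrier_counts = counts)
}

#' Apply the deleteriousness filter
#'
#' @param variants annotated variant data.frame with `sift_call` /
#'   `polyphen_call` columns.
#' @param rule a [deleteriousness_rule()].
#' @return list with `retained`, `verdict` and `n_unscored` (variants
#'   removed because both predictions were absent).
#' @export
deleteriousness_filter <- function(variants, rule = deleteriousness_rule()) {
  stopifnot(inherits(rule, "deleteriousness_rule"))
  sift_dam <- !is.na(variants$sift_call) & variants$sift_call == "deleterious"
  poly_dam <- !is.na(variants$polyphen_call) &
    variants$polyphen_call %in% rule$damaging_polyphen_levels
  both_absent <- is.na(variants$sift_call) & is.na(variants$polyphen_call)
  verdict <- switch(rule$require,
    either = sift_dam | poly_dam,
    both = sift_dam & poly_dam,
    sift_only = sift_dam,
    polyphen_only = poly_dam)
  verdict <- verdict & !both_absent
  if (any(both_absent)) {
    message(sprintf("deleteriousness_filter: %d variant(s) removed with no prediction call",
                    sum(both_absent)))
  }
  list(retained = variants[verdict, , drop = FALSE], verdict = verdict,
       n_unscored = sum(both_absent))
}

#' Run the full SNV candidate cascade
#'
#' Applies, in order, the frequency, segregation and deleteriousness
#' filters (the stages are pure intersections, so the order does not change
#' the final set) and returns the surviving candidates with their filter
#' trail and per-class carrier counts. Candidate rows are ordered by
#' `(chrom, pos, ref, alt)`.
#'
#' @param variants annotated variant data.frame.
#' @param genotypes integer matrix of alt-allele counts.
#' @param ped a [pedigree()].
#' @param rules list with elements `frequency`, `segregation`,
#'   `deleteriousness` (defaults used for any omitted element).
#' @return list of class `"snv_cascade"` with `candidates` (data.frame
#'   including carrier-count and filter-trail columns), `stage_counts`
#'   (variants surviving each stage) and `verdicts` (per-stage logical
#'   matrix over all input variants).
#' @examples
#' fx <- build_family_fixture()
#' res <- run_snv_cascade(fx$annotations, fx$genotypes, fx$pedigree)
#' nrow(res$candidates)  # 3
#' @export
run_snv_cascade <- function(variants, genotypes, ped, rules = list()) {
  fr <- rules$frequency %||% frequency_rule()
  sr <- rules$segregation %||% segregation_rule()
  dr <- rules$deleteriousness %||% deleteriousness_rule()

  f <- frequency_filter(variants, fr)
  s <- segregation_filter(variants, genotypes, ped, sr)
  d <- deleteriousness_filter(variants, dr)
  keep <- f$verdict & s$verdict & d$verdict

  cand <- variants[keep, , drop = FALSE]
  counts <- s$carrier_counts[keep, , drop = FALSE]
  cand$carriers_mplc <- counts[, "MPLC"]
  cand$carriers_nodule <- counts[, "NODULE"]
  cand$carriers_unaffected <- counts[, "UNAFFECTED"]
  cand$carriers_total <- rowSums(counts[, c("MPLC", "NODULE", "UNAFFECTED"), drop = FALSE])
  cand$pass_frequency <- rep(TRUE, nrow(cand))
  cand$pass_segregation <- rep(TRUE, nrow(cand))
  cand$pass_deleteriousness <- rep(TRUE, nrow(cand))
  ord <- order(cand$chrom, cand$pos, cand$ref, cand$alt)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL

  structure(list(
    candidates = cand,
    stage_counts = c(input = nrow(variants),
                     after_frequency = sum(f$verdict),
                     after_segregation = sum(f$verdict & s$verdict),
                     after_deleteriousness = sum(keep)),
    verdicts = cbind(frequency = f$verdict, segregation = s$verdict,
                     deleteriousness = d$verdict),
    rules = list(frequency = fr, segregation = sr, deleteriousness = dr)
  ), class = "snv_cascade")
}

#' @method print snv_cascade
#' @export
print.snv_cascade <- function(x, ...) {
  cat("<snv_cascade>\n  stage counts:",
      paste(sprintf("%s=%d", names(x$stage_counts), x$stage_counts), collapse = " -> "),
      "\n")
  cat(sprintf("  %d candidate(s)\n", nrow(x$candidates)))
  invisible(x)
}

#' Cohort carrier frequency with an exact binomial interval
#'
#' Point estimate `n_carriers / n_total` with a Clopper-Pearson exact 95%
#' confidence interval. The percentage rendering rounds half-up to one
#' decimal (6/162 renders as "3.7").
#'
#' @param n_carriers carriers observed in the validation cohort.
#' @param n_total cohort size (> 0).
#' @param conf_level confidence level (default 0.95).
#' @return list of class `"cohort_screen"` with `n_carriers`, `n_total`,
#'   `frequency`, `ci95`, `percent` (one-decimal character rendering) and
#'   `method`.
#' @examples
#' carrier_frequency(6, 162)$percent  # "3.7"
#' @export
carrier_frequency <- function(n_carriers, n_total, conf_level = 0.95) {
  if (!is_count(n_carriers) || !is_count(n_total)) stopf("counts must be non-negative integers")
  if (n_total == 0) stopf("n_total must be > 0")
  if (n_carriers > n_total) stopf("n_carriers exceeds n_total")
  ci <- stats::binom.test(n_carriers, n_total, conf.level = conf_level)$conf.int
  freq <- n_carriers / n_total
  structure(list(
    n_carriers = as.integer(n_carriers), n_total = as.integer(n_total),
    frequency = freq, ci95 = c(low = ci[1], high = ci[2]),
    percent = format_percent1(freq), method = "clopper-pearson"
  ), class = "cohort_screen")
}

# Round half-up to one decimal on the percent scale (3.7037 -> "3.7";
# 2.25 -> "2.3", unlike banker's rounding).
format_percent1 <- function(freq) {
  sprintf("%.1f", floor(freq * 1000 + 0.5) / 10)
}

#' @method print cohort_screen
#' @export
print.cohort_screen <- function(x, ...) {
  cat(sprintf("<cohort_screen> %d/%d carriers = %s%% (95%% CI %.4f-%.4f, %s)\n",
              x$n_carriers, x$n_total, x$percent, x$ci95[1], x$ci95[2], x$method))
  invisible(x)
}
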