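# Quantitative models for the functional assays: single-hit Poisson
# limiting-dilution frequency (ELDA-style), likelihood-ratio group
# comparison, delta-delta-Ct relative expression, and ellipsoid tumor
# volume.

validate_ld_table <- function(table) {
  stopifnot(all(c("dose", "n_tested", "n_positive") %in% names(table)))
  if (nrow(table) == 0L) stopf("limiting-dilution table has no rows")
  if (any(table$dose <= 0)) stopf("doses must be positive")
  if (any(table$n_positive < 0 | table$n_positive > table$n_tested)) {
    stopf("n_positive must lie in [0, n_tested]")
  }
  invisible(table)
}

# Binomial log-likelihood of the single-hit model at frequency f:
# P(positive | dose d) = 1 - exp(-f d).
loglik_single_hit <- function(f, table) {
  if (f < 0) return(-Inf)
  d <- table$dose; n <- table$n_tested; k <- table$n_positive
  if (f == 0) return(if (sum(k) > 0) -Inf else 0)
  # log(1 - exp(-fd)) via expm1 for numerical stability at small fd
  lp <- log(-expm1(-f * d))
  sum(k * lp) + sum((n - k) * (-f * d))
}

# Score d loglik / d f (interior optimum satisfies score = 0).
score_single_hit <- function(f, table) {
  d <- table$dose; n <- table$n_tested; k <- table$n_positive
  e <- exp(-f * d)
  sum(k * d * e / (1 - e)) - sum((n - k) * d)
}

#' Single-hit Poisson stem-cell frequency estimate
#'
#' Fits `P(positive at dose d) = 1 - exp(-f d)` to a limiting-dilution
#' outcome table by maximizing the binomial log-likelihood over `f > 0`
#' (optimization on `log f` for stability), and inverts the likelihood
#' ratio (chi-squared with 1 df at level 0.95, i.e. deviance 3.84) for the
#' confidence interval, solved to tolerance 1e-8 on `log f`.
#'
#' Boundary designs are reported, not refused: a table with no positive
#' outcome yields `f_hat = 0` with a one-sided upper bound; a table with
#' every animal positive yields an infinite maximum-likelihood estimate,
#' flagged, with a one-sided lower bound.
#'
#' @param table data.frame with columns `dose`, `n_tested`, `n_positive`
#'   (and optionally `group`).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list of class `"stem_frequency"`: `f_hat`, `ci95` (`low`,
#'   `high`), `loglik`, `boundary` (`"none"`, `"all_negative"` or
#'   `"all_positive"`), `model`.
#' @examples
#' tab <- data.frame(dose = 1000, n_tested = 10, n_positive = 5)
#' fit_single_hit(tab)$f_hat  # -log(0.5)/1000
#' @export
fit_single_hit <- function(table, conf_level = 0.95) {
  validate_ld_table(table)
  crit <- stats::qchisq(conf_level, df = 1)
  k_tot <- sum(table$n_positive)
  n_tot <- sum(table$n_tested)
  nd <- sum(table$n_tested * table$dose)

  if (k_tot == 0L) {
    # likelihood maximal at f = 0 (loglik 0); LR upper bound in closed form
    upper <- crit / 2 / nd
    return(structure(list(f_hat = 0, ci95 = c(low = 0, high = upper),
                          loglik = 0, boundary = "all_negative",
                          model = "single-hit Poisson"), class = "stem_frequency"))
  }
  if (k_tot == n_tot && all(table$n_positive == table$n_tested)) {
    # likelihood increasing in f; supremum loglik is 0
    dev <- function(lf) -2 * loglik_single_hit(exp(lf), table) - crit
    lo <- log(1 / max(table$dose)) - 20
    hi <- log(1 / min(table$dose)) + 20
    while (dev(lo) < 0) lo <- lo - 5
    lower <- exp(stats::uniroot(dev, c(lo, hi), tol = 1e-8)$root)
    return(structure(list(f_hat = Inf, ci95 = c(low = lower, high = Inf),
                          loglik = 0, boundary = "all_positive",
                          model = "single-hit Poisson"), class = "stem_frequency"))
  }

  # interior MLE: coarse optimize on log f, then polish the score root
  obj <- function(lf) -loglik_single_hit(exp(lf), table)
  lo <- log(-log1p(-k_tot / (n_tot + 1)) / max(table$dose)) - 10
  hi <- log(-log1p(-k_tot / (n_tot + 1)) / min(table$dose)) + 10
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
  lf_hat <- opt$minimum
  sc <- function(lf) score_single_hit(exp(lf), table)
  bl <- lf_hat - 0.5; bu <- lf_hat + 0.5
  while (sc(bl) < 0) bl <- bl - 0.5
  while (sc(bu) > 0) bu <- bu + 0.5
  lf_hat <- stats::uniroot(sc, c(bl, bu), tol = 1e-13)$root
  f_hat <- exp(lf_hat)
  ll_max <- loglik_single_hit(f_hat, table)

  dev <- function(lf) 2 * (ll_max - loglik_single_hit(exp(lf), table)) - crit
  lo_b <- lf_hat - 1
  while (dev(lo_b) < 0) lo_b <- lo_b - 1
  hi_b <- lf_hat + 1
  while (dev(hi_b) < 0) hi_b <- hi_b + 1
  lower <- exp(stats::uniroot(dev, c(lo_b, lf_hat), tol = 1e-8)$root)
  upper <- exp(stats::uniroot(dev, c(lf_hat, hi_b), tol = 1e-8)$root)

  structure(list(f_hat = f_hat, ci95 = c(low = lower, high = upper),
                 loglik = ll_max, boundary = "none",
                 model = "single-hit Poisson"), class = "stem_frequency")
}

#' @method print stem_frequency
#' @export
print.stem_frequency <- function(x, ...) {
  cat(sprintf("<stem_frequency> f = %.4g (1 in %.4g), 95%% CI [%.4g, %.4g]%s\n",
              x$f_hat, 1 / x$f_hat, x$ci95[1], x$ci95[2],
              if (x$boundary != "none") paste0(" [boundary: ", x$boundary, "]") else ""))
  invisible(x)
}

#' Likelihood-ratio comparison of two limiting-dilution groups
#'
#' Compares the model with one shared frequency against separate per-group
#' frequencies; `2 * (loglik_separate - loglik_shared)` is referred to a
#' chi-squared distribution with 1 df. When any component estimate sits on
#' a boundary the p-value is flagged approximate.
#'
#' @param table_a,table_b limiting-dilution tables (see
#'   [fit_single_hit()]).
#' @return list with `statistic`, `p_value`, `f_a`, `f_b`, `f_shared`,
#'   `approximate`.
#' @export
compare_frequencies <- function(table_a, table_b) {
  fit_a <- fit_single_hit(table_a)
  fit_b <- fit_single_hit(table_b)
  pooled <- rbind(table_a[c("dose", "n_tested", "n_positive")],
                  table_b[c("dose", "n_tested", "n_positive")])
  fit_s <- fit_single_hit(pooled)
  stat <- max(0, 2 * (fit_a$loglik + fit_b$loglik - fit_s$loglik))
  approx <- any(c(fit_a$boundary, fit_b$boundary, fit_s$boundary) != "none")
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       f_a = fit_a$f_hat, f_b = fit_b$f_hat, f_shared = fit_s$f_hat,
       approximate = approx)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per record, `dCt = target_ct - reference_ct` (normalization to the
#' endogenous control, e.g. beta-actin). Technical replicates sharing a
#' sample label are averaged first (the default), then `dCt` is averaged
#' per condition; `ddCt` is taken against the control condition and the
#' fold change is `2^-ddCt`, so the control condition's fold is 1 by
#' construction.
#'
#' @param records data.frame with columns `sample`, `condition`,
#'   `target_ct`, `reference_ct`.
#' @param control_condition label of the reference condition.
#' @param aggregate_technical average replicate rows per sample before
#'   averaging per condition (default TRUE).
#' @return data.frame with `condition`, `mean_dct`, `ddct`, `fold`.
#' @examples
#' rec <- data.frame(sample = c("s1", "s2"), condition = c("vector", "mutant"),
#'                   target_ct = c(24, 22), reference_ct = c(18, 18))
#' relative_expression(rec, "vector")
#' @export
relative_expression <- function(records, control_condition,
                                aggregate_technical = TRUE) {
  stopifnot(all(c("sample", "condition", "target_ct", "reference_ct") %in% names(records)))
  if (!control_condition %in% records$condition) {
    stopf("control condition '%s' absent from the records", control_condition)
  }
  if (any(!is.finite(records$target_ct)) || any(!is.finite(records$reference_ct))) {
    stopf("Ct values must be finite")
  }
  records$dct <- records$target_ct - records$reference_ct
  if (aggregate_technical) {
    per_sample <- stats::aggregate(dct ~ sample + condition, records, mean)
  } else {
    per_sample <- records[, c("sample", "condition", "dct")]
  }
  per_cond <- stats::aggregate(dct ~ condition, per_sample, mean)
  names(per_cond)[2] <- "mean_dct"
  ctrl <- per_cond$mean_dct[per_cond$condition == control_condition]
  per_cond$ddct <- per_cond$mean_dct - ctrl
  per_cond$fold <- 2^(-per_cond$ddct)
  per_cond[order(per_cond$condition != control_condition, per_cond$condition), ,
           drop = FALSE]
}

#' Ellipsoid tumor volume
#'
#' `volume = length * width^2 / 2`, in cubic units of the inputs
#' (conventionally mm).
#'
#' @param length,width caliper measurements (mm); vectors are accepted and
#'   recycled. Measurements where width exceeds length trigger a warning
#'   (the convention takes length as the longer axis) but are still
#'   computed.
#' @return numeric vector of volumes (mm^3).
#' @examples
#' tumor_volume(10, 6)  # 180
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) stopf("measurements must be non-negative")
  if (any(width > length)) warnf("width exceeds length for %d measurement(s)",
                                 sum(width > length))
  length * width^2 / 2
}
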