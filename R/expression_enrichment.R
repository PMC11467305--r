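# Expression module: threshold differential-expression calls, cross-cell-
# line intersection, hypergeometric over-representation against curated
# gene sets, and a permutation-based gene set enrichment score (GSEA) with
# gene-label permutation.

#' Threshold differential expression between two conditions
#'
#' Computes per-gene `log2fc = log2(mean_b + pseudocount) -
#' log2(mean_a + pseudocount)` on linear-scale expression values and calls
#' a gene differential when `|log2fc|` strictly exceeds the threshold: a
#' gene at exactly the threshold is never differential. No dispersion-based
#' test is applied — the design carries single profiles per condition.
#'
#' @param expr numeric matrix, genes x samples, linear scale.
#' @param conditions data.frame mapping `sample` to `condition` (as
#'   returned by [simulate_expression()]).
#' @param group_a,group_b condition labels (fold change is b relative
#'   to a).
#' @param pseudocount value added to group means before taking logs
#'   (>= 0; default 0, suitable for strictly positive intensities; use
#'   e.g. 0.5 for counts).
#' @param threshold `|log2fc|` cutoff (strict; default 1).
#' @return data.frame with `gene`, `mean_a`, `mean_b`, `log2fc`, `is_de`.
#' @export
compute_log2fc <- function(expr, conditions, group_a, group_b,
                           pseudocount = 0, threshold = 1) {
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  cols_a <- conditions$sample[conditions$condition == group_a]
  cols_b <- conditions$sample[conditions$condition == group_b]
  if (length(cols_a) == 0L) stopf("no samples for condition '%s'", group_a)
  if (length(cols_b) == 0L) stopf("no samples for condition '%s'", group_b)
  mean_a <- rowMeans(expr[, cols_a, drop = FALSE])
  mean_b <- rowMeans(expr[, cols_b, drop = FALSE])
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  data.frame(gene = rownames(expr), mean_a = mean_a, mean_b = mean_b,
             log2fc = log2fc, is_de = abs(log2fc) > threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect differential genes across two cell lines
#'
#' @param results_a,results_b data.frames from [compute_log2fc()].
#' @param direction_consistent when TRUE, the fold changes must agree in
#'   sign as well.
#' @return character vector of genes differential in both inputs.
#' @export
intersect_de <- function(results_a, results_b, direction_consistent = TRUE) {
  de_a <- results_a[results_a$is_de, c("gene", "log2fc")]
  de_b <- results_b[results_b$is_de, c("gene", "log2fc")]
  shared <- merge(de_a, de_b, by = "gene", suffixes = c("_a", "_b"))
  if (direction_consistent) {
    shared <- shared[sign(shared$log2fc_a) == sign(shared$log2fc_b), , drop = FALSE]
  }
  sort(shared$gene)
}

#' Over-representation of curated gene sets in a differential-gene list
#'
#' For each curated set, counts the overlap with the differential genes and
#' computes a hypergeometric enrichment p-value
#' (`P[X >= overlap]` drawing `|de_genes|` genes from a universe containing
#' `|set within universe|` successes).
#'
#' @param de_genes character vector of differential genes.
#' @param curated_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of all measured genes.
#' @return data.frame with one row per set: `set`, `set_size` (within the
#'   universe), `overlap`, `p_hyper`, and a comma-separated
#'   `overlap_genes` column.
#' @export
gene_set_overlap <- function(de_genes, curated_sets, universe) {
  if (length(curated_sets) == 0L) stopf("no curated sets supplied")
  de_genes <- intersect(unique(de_genes), universe)
  N <- length(universe)
  rows <- lapply(names(curated_sets), function(nm) {
    s <- intersect(curated_sets[[nm]], universe)
    if (length(curated_sets[[nm]]) > N) {
      stopf("gene set '%s' is larger than the measured universe", nm)
    }
    ov <- intersect(de_genes, s)
    p <- stats::phyper(length(ov) - 1L, length(s), N - length(s),
                       length(de_genes), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = length(ov),
               p_hyper = p, overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_hyper, out$set), , drop = FALSE]
}

#' Build a ranked profile from a statistic vector
#'
#' Orders genes by decreasing statistic, breaking ties by gene label so the
#' order is fully deterministic.
#'
#' @param stat named numeric vector (e.g. log2 fold changes).
#' @return data.frame with `gene` and `stat`, strictly ordered.
#' @export
rank_profile <- function(stat) {
  if (is.null(names(stat))) stopf("the ranking statistic must be named by gene")
  if (anyDuplicated(names(stat))) stopf("duplicate gene labels in the profile")
  ord <- order(-stat, names(stat))
  data.frame(gene = names(stat)[ord], stat = as.numeric(stat)[ord],
             stringsAsFactors = FALSE)
}

#' Gene set enrichment score (running-sum statistic)
#'
#' Walks the ranked profile from top to bottom; at an in-set gene the
#' running sum increases by `|stat|^weight_p` normalized by the total
#' in-set `|stat|^weight_p` mass, at an out-of-set gene it decreases by
#' `1 / (N - |S|)`. The enrichment score is the signed maximum deviation of
#' this running sum from zero, and lies in `[-1, 1]`.
#'
#' @param profile a [rank_profile()] data.frame.
#' @param gene_set character vector of set members.
#' @param weight_p non-negative statistic weight (0 gives the unweighted
#'   Kolmogorov-Smirnov-like statistic; 1 is the conventional weighting).
#' @return the enrichment score (single numeric).
#' @examples
#' prof <- rank_profile(c(a = 5, b = 4, c = 3, d = 2, e = 1))
#' gsea_es(prof, c("a", "c"), weight_p = 0)  # 2/3
#' @export
gsea_es <- function(profile, gene_set, weight_p = 1) {
  if (weight_p < 0) stopf("weight_p must be >= 0")
  hits <- profile$gene %in% gene_set
  n_hit <- sum(hits)
  N <- nrow(profile)
  if (n_hit == 0L) stopf("gene set does not intersect the profile: ES undefined")
  if (n_hit == N) stopf("gene set covers the entire profile: ES undefined")
  w <- abs(profile$stat)^weight_p
  hit_mass <- sum(w[hits])
  step <- ifelse(hits,
                 if (hit_mass > 0) w / hit_mass else 1 / n_hit,
                 -1 / (N - n_hit))
  # zero in-set weight mass (all-zero stats at weight_p > 0): uniform steps
  if (weight_p > 0 && hit_mass == 0) step[hits] <- 1 / n_hit
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Permutation p-value and significance call for a gene set
#'
#' The null distribution is built from random gene sets of the same size
#' drawn without replacement from the profile (gene-label permutation; the
#' single-profile-per-condition design precludes phenotype permutation).
#' The one-sided p-value uses the add-one correction
#' `p = (1 + #(null ES >= observed)) / (n_perm + 1)` for a positive
#' observed score and the mirrored tail for a negative one, so `p` is never
#' 0 and never exceeds 1. The default significance call requires
#' `ES > es_min` and `p < p_max`.
#'
#' Note that the sign-mirrored p (`alternative = "auto"`) is a reporting
#' convention, not a calibrated tail probability: under a null profile it
#' concentrates below 0.5 because each observed score is referred to its
#' own tail. For calibration checks use a fixed direction
#' (`alternative = "greater"` or `"less"`), whose p-value is uniform under
#' the null.
#'
#' @inheritParams gsea_es
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param es_min ES threshold for the significance call (default 0.4).
#' @param p_max p-value threshold (default 0.05).
#' @param alternative `"auto"` (tail chosen by the sign of the observed
#'   score; the default), `"greater"` (upper tail) or `"less"` (lower
#'   tail).
#' @return list of class `"gsea_result"`: `set_size`, `es`, `p_perm`,
#'   `n_perm`, `significant`.
#' @export
gsea_permutation_p <- function(profile, gene_set, weight_p = 1,
                               n_perm = 1000L, seed = 1L,
                               es_min = 0.4, p_max = 0.05,
                               alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is_count(n_perm) || n_perm < 1) stopf("n_perm must be >= 1")
  hits <- profile$gene %in% gene_set
  k <- sum(hits)
  if (k >= nrow(profile)) stopf("gene set must be smaller than the profile")
  es_obs <- gsea_es(profile, gene_set, weight_p)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      gsea_es(profile, sample(profile$gene, k), weight_p)
    }, numeric(1))
  })
  dir <- switch(alternative, auto = if (es_obs >= 0) "greater" else "less",
                alternative)
  p <- if (dir == "greater") {
    (1 + sum(null_es >= es_obs)) / (n_perm + 1)
  } else {
    (1 + sum(null_es <= es_obs)) / (n_perm + 1)
  }
  structure(list(set_size = k, es = es_obs, p_perm = p, n_perm = as.integer(n_perm),
                 significant = es_obs > es_min && p < p_max),
            class = "gsea_result")
}

#' @method print gsea_result
#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> |S|=%d ES=%.3f p=%.4g (%d perms) %s\n",
              x$set_size, x$es, x$p_perm, x$n_perm,
              if (x$significant) "SIGNIFICANT" else "n.s."))
  invisible(x)
}
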