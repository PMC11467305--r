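# Independent brute-force oracles and small builders shared across tests.

# Exhaustive segregation oracle: loops over variants and members with no
# vectorization, mirroring the rule definition literally.
brute_force_segregation <- function(genotypes, ped, min_carriers,
                                    max_unaffected = 0L) {
  keep <- logical(nrow(genotypes))
  for (v in seq_len(nrow(genotypes))) {
    counts <- c(MPLC = 0L, NODULE = 0L, UNAFFECTED = 0L, UNKNOWN = 0L)
    for (m in seq_len(nrow(ped))) {
      g <- genotypes[v, ped$id[m]]
      if (!is.na(g) && g >= 1) {
        counts[ped$phenotype[m]] <- counts[ped$phenotype[m]] + 1L
      }
    }
    ok <- TRUE
    for (cls in names(min_carriers)) {
      if (counts[cls] < min_carriers[[cls]]) ok <- FALSE
    }
    if (counts["UNAFFECTED"] > max_unaffected) ok <- FALSE
    keep[v] <- ok
  }
  keep
}

# Exhaustive per-group tally for SV events.
brute_force_recurrence <- function(events, ped) {
  out <- matrix(0L, nrow(events), 4,
                dimnames = list(events$id,
                                c("MPLC", "NODULE", "UNAFFECTED", "UNKNOWN")))
  for (e in seq_len(nrow(events))) {
    for (m in seq_len(nrow(ped))) {
      if (events[[ped$id[m]]][e] != 0) {
        out[e, ped$phenotype[m]] <- out[e, ped$phenotype[m]] + 1L
      }
    }
  }
  out
}

# Random pedigree of the family's class structure with fully random
# genotypes (no transmission structure): stress input for filter oracles.
random_ped_and_gt <- function(n_variants, seed) {
  set.seed(seed)
  ped <- pedigree(id = sprintf("P%02d", 1:15),
                  phenotype = sample(c(rep("MPLC", 5), rep("NODULE", 9), "UNAFFECTED")))
  gt <- matrix(sample(0:2, n_variants * 15, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1)),
               nrow = n_variants, dimnames = list(NULL, ped$id))
  storage.mode(gt) <- "integer"
  list(ped = ped, gt = gt)
}

# Hand-written hypergeometric upper-tail by combinatorial enumeration.
enum_hyper_tail <- function(overlap, set_size, universe_size, draw_size) {
  ks <- overlap:min(set_size, draw_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, draw_size - ks)) /
    choose(universe_size, draw_size)
}

make_sv_row <- function(id, present, ped, region_class = "non_exonic") {
  df <- data.frame(id = id, type = "deletion", chrom1 = "1", pos1 = 100L,
                   chrom2 = "1", pos2 = 200L, gene = id,
                   region_class = region_class, stringsAsFactors = FALSE)
  for (i in seq_along(ped$id)) df[[ped$id[i]]] <- present[i]
  df
}
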