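# Deterministic 15-member family fixture: a synthetic stand-in for the
# study's WGS data (which is not publicly retrievable), built so that the
# printed carrier patterns hold by construction.

#' Deterministic synthetic family fixture
#'
#' Builds, with a fixed internal seed, a synthetic 15-member pedigree
#' (5 MPLC, 9 nodule, 1 unaffected member) together with a genotype matrix,
#' an annotation table and a structural-variant event table that reproduce
#' the carrier patterns of the motivating family study:
#'
#' * three planted candidate SNVs, each heterozygous in all 5 MPLC members
#'   and in 8 of the 9 nodule members, absent from the unaffected member
#'   (13 of 15 carriers), with population allele frequencies below 1% (or
#'   absent, i.e. novel) and deleterious SIFT/PolyPhen calls;
#' * 210 background SNVs, each violating at least one cascade rule
#'   (common, or benign-predicted, or mis-segregating);
#' * two planted non-exonic SV events present in all 5 cancer-group and all
#'   9 nodule-group members and absent from the control member, plus 24
#'   background events that are each either under-recurrent or carried by
#'   the control member.
#'
#' The topology is two generations of dominant transmission: the five MPLC
#' members are founder siblings, the remaining ten members their children
#' (married-in parents ungenotyped). Gene labels are synthetic.
#'
#' Repeated calls return byte-identical objects.
#'
#' @return list with elements `pedigree`, `genotypes`, `annotations`, `sv`.
#' @examples
#' fx <- build_family_fixture()
#' sum(fx$genotypes[1, ] >= 1)  # 13 carriers among the 15 members
#' @export
build_family_fixture <- function() {
  ids <- c(sprintf("MPLC_%d", 1:5), sprintf("NODULE_%d", 1:9), "UNAFFECTED_1")
  pheno <- c(rep("MPLC", 5), rep("NODULE", 9), "UNAFFECTED")
  father <- c(rep(NA_character_, 5),
              c("MPLC_1", "MPLC_1", "MPLC_2", "MPLC_2", "MPLC_3",
                "MPLC_3", "MPLC_4", "MPLC_4", "MPLC_5"),
              "MPLC_5")
  ped <- pedigree(id = ids, father_id = father, mother_id = NA_character_,
                  sex = c(1, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2, 1, 2),
                  phenotype = pheno)

  carriers13 <- c(rep(1L, 5), rep(1L, 8), 0L, 0L)  # all but NODULE_9, UNAFFECTED_1

  planted_ann <- data.frame(
    chrom = "17", pos = c(41170000L, 41250000L, 41330000L),
    ref = c("C", "G", "C"), alt = c("T", "A", "T"),
    gene = c("CAND1", "CAND2", "CAND3"),
    af_1kg_eas = c(NA, 0.002, 0.005),
    af_esp = c(NA, 0.001, 0.004),
    af_esp6500 = c(NA, 0.003, 0.006),
    sift_call = "deleterious",
    polyphen_call = c("probably_damaging", "probably_damaging", "possibly_damaging"),
    region_class = "exonic", stringsAsFactors = FALSE
  )
  gt_planted <- matrix(rep(carriers13, each = 3), nrow = 3,
                       dimnames = list(NULL, ids))

  with_seed(20240915L, {
    nbg <- 210L
    mode <- rep_len(c("common", "benign", "misseg"), nbg)
    af <- numeric(nbg)
    af[mode == "common"] <- 0.02 + (seq_len(sum(mode == "common")) %% 30) / 100
    af[mode == "benign"] <- 0.001
    af[mode == "misseg"] <- NA  # novel but mis-segregating
    ann_bg <- data.frame(
      chrom = as.character((seq_len(nbg) %% 22L) + 1L),
      pos = 1000000L + 1371L * seq_len(nbg),
      ref = "A", alt = "G", gene = sprintf("BG_%03d", seq_len(nbg)),
      af_1kg_eas = af, af_esp = af, af_esp6500 = af,
      sift_call = ifelse(mode == "benign", "tolerated", "deleterious"),
      polyphen_call = ifelse(mode == "benign", "benign", "probably_damaging"),
      region_class = "exonic", stringsAsFactors = FALSE
    )
    gt_bg <- matrix(0L, nrow = nbg, ncol = 15L, dimnames = list(NULL, ids))
    for (i in seq_len(nbg)) {
      if (mode[i] == "misseg") {
        # rare + deleterious, but fails segregation: either carried by the
        # unaffected member or present in too few MPLC members
        if (i %% 2L == 0L) {
          gt_bg[i, "UNAFFECTED_1"] <- 1L
          gt_bg[i, sample(ids[1:14], 6L)] <- 1L
        } else {
          gt_bg[i, sample(ids[1:5], 3L)] <- 1L
        }
      } else {
        # genotype pattern irrelevant: these fail frequency or prediction
        gt_bg[i, ] <- stats::rbinom(15L, 2L, min(if (is.na(af[i])) 0.05 else af[i], 0.5))
      }
    }

    ann <- rbind(planted_ann, ann_bg)
    gt <- rbind(gt_planted, gt_bg)
    storage.mode(gt) <- "integer"
    rownames(gt) <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)

    sv <- fixture_sv_table(ped)

    list(pedigree = ped, genotypes = gt, annotations = ann, sv = sv)
  })
}

# Two planted recurrent non-exonic events plus background events that are
# each either under-recurrent or present in the control member.
fixture_sv_table <- function(ped) {
  ids <- ped$id
  rows <- list()
  all_but_control <- stats::setNames(as.integer(ids != "UNAFFECTED_1"), ids)
  rows[[1]] <- sv_event_row("SV_PLANT_1", type = "deletion", gene = "SVGENE1",
                            region_class = "non_exonic", present = all_but_control,
                            pos_seed = 1000L)
  rows[[2]] <- sv_event_row("SV_PLANT_2", type = "translocation", gene = "SVGENE2",
                            region_class = "non_exonic", present = all_but_control,
                            pos_seed = 2000L)
  for (k in 1:24) {
    present <- stats::setNames(integer(15L), ids)
    if (k %% 2L == 0L) {
      # recurrent enough but carried by the control member
      present[] <- 1L
    } else {
      # under-recurrent: too few cancer-group carriers
      present[sample(ids[1:5], 3L)] <- 1L
      present[sample(ids[6:14], 9L)] <- 1L
    }
    rows[[k + 2L]] <- sv_event_row(sprintf("SV_BG_%02d", k),
                                   type = SV_TYPES[(k %% 4L) + 1L],
                                   gene = sprintf("SVBG_%02d", k),
                                   region_class = if (k %% 3L == 0L) "exonic" else "non_exonic",
                                   present = present, pos_seed = 50000L + 1000L * k)
  }
  sv <- do.call(rbind, rows)
  rownames(sv) <- NULL
  class(sv) <- c("sv_table", "data.frame")
  sv
}
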