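#' Construct and validate a pedigree
#'
#' A pedigree is a `data.frame` with one row per member and columns `id`,
#' `father_id`, `mother_id`, `sex` and `phenotype`. Parent ids may be `NA`
#' (founder, or parent not genotyped); when present they may reference
#' another member row, in which case the reference must resolve and must not
#' create a cycle. The phenotype takes one of the classes
#' `"MPLC"`, `"NODULE"`, `"UNAFFECTED"`, `"UNKNOWN"`; `UNKNOWN` members are
#' ignored by every downstream filter.
#'
#' @param id character vector of unique member ids.
#' @param father_id,mother_id character vectors of parent ids (`NA` when
#'   absent). A parent id not present in `id` refers to an ungenotyped
#'   individual and is kept as-is.
#' @param sex integer vector (1 = male, 2 = female, 0/NA = unknown).
#' @param phenotype character vector of phenotype classes.
#' @return A `data.frame` of class `"pedigree"`.
#' @examples
#' ped <- pedigree(
#'   id = c("F1", "C1"), father_id = c(NA, "F1"), mother_id = c(NA, NA),
#'   sex = c(1, 2), phenotype = c("MPLC", "NODULE")
#' )
#' pedigree_class_counts(ped)
#' @export
pedigree <- function(id, father_id = NA_character_, mother_id = NA_character_,
                     sex = NA_integer_, phenotype = "UNKNOWN") {
  n <- length(id)
  ped <- data.frame(
    id = as.character(id),
    father_id = rep_len(as.character(father_id), n),
    mother_id = rep_len(as.character(mother_id), n),
    sex = rep_len(as.integer(sex), n),
    phenotype = rep_len(as.character(phenotype), n),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  if (nrow(ped) == 0L) stopf("pedigree has no members")
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup)) stopf("duplicate member id(s): %s", paste(unique(dup), collapse = ", "))
  bad <- setdiff(ped$phenotype, PHENO_CLASSES)
  if (length(bad)) {
    stopf("unknown phenotype class(es): %s (row %s)", paste(bad, collapse = ", "),
          paste(which(ped$phenotype %in% bad), collapse = ", "))
  }
  # self-parenthood / cycles among members present in the table
  for (col in c("father_id", "mother_id")) {
    self <- which(!is.na(ped[[col]]) & ped[[col]] == ped$id)
    if (length(self)) stopf("member '%s' is its own parent (row %d)", ped$id[self[1]], self[1])
  }
  parent_of <- function(i) {
    p <- c(ped$father_id[i], ped$mother_id[i])
    match(p[!is.na(p)], ped$id, nomatch = 0L)
  }
  for (i in seq_len(nrow(ped))) {
    seen <- integer(0)
    frontier <- parent_of(i)
    while (length(frontier)) {
      frontier <- frontier[frontier > 0L]
      if (i %in% frontier) stopf("member '%s' is its own ancestor", ped$id[i])
      seen <- union(seen, frontier)
      frontier <- setdiff(unlist(lapply(frontier, parent_of)), seen)
    }
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Count pedigree members per phenotype class
#'
#' @param ped a [pedigree()].
#' @return Named integer vector over the four phenotype classes.
#' @export
pedigree_class_counts <- function(ped) {
  tab <- table(factor(ped$phenotype, levels = PHENO_CLASSES))
  stats::setNames(as.integer(tab), names(tab))
}

#' Member ids belonging to one phenotype class
#' @param ped a [pedigree()].
#' @param class phenotype class label.
#' @return Character vector of member ids.
#' @export
members_of_class <- function(ped, class) {
  ped$id[ped$phenotype == class]
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  cc <- pedigree_class_counts(x)
  cat(sprintf("<pedigree> %d members (%s)\n", nrow(x),
              paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
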