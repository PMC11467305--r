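# SV recurrence screen: per-group carrier counts ("rec"), group thresholds,
# control exclusion, and exonic/non-exonic flagging. "rec" is the number of
# members of a phenotype group carrying a given event; thresholds compare
# with >=.

#' Recurrence rule for the structural-variant screen
#'
#' @param min_rec named minimum per-group carrier counts; group labels are
#'   phenotype classes (defaults: 5 in the cancer group, 9 in the nodule
#'   group).
#' @param exclude_groups phenotype classes treated as controls (default
#'   `"UNAFFECTED"`).
#' @param require_absent_in_excluded when TRUE (default) an event carried
#'   by any excluded-group member is removed; when FALSE the excluded group
#'   is merely ignored.
#' @return list of class `"recurrence_rule"`.
#' @export
recurrence_rule <- function(min_rec = c(MPLC = 5L, NODULE = 9L),
                            exclude_groups = "UNAFFECTED",
                            require_absent_in_excluded = TRUE) {
  if (is.null(names(min_rec)) || !all(names(min_rec) %in% PHENO_CLASSES)) {
    stopf("min_rec must be named with phenotype classes")
  }
  if (any(min_rec < 0)) stopf("min_rec counts must be >= 0")
  bad <- setdiff(exclude_groups, PHENO_CLASSES)
  if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  structure(list(min_rec = min_rec, exclude_groups = exclude_groups,
                 require_absent_in_excluded = isTRUE(require_absent_in_excluded)),
            class = "recurrence_rule")
}

#' Per-event, per-group carrier counts
#'
#' @param events an SV event table (see [read_sv_table()]): metadata
#'   columns plus one 0/1 presence column per pedigree member.
#' @param ped a [pedigree()]; presence columns must cover exactly its
#'   members.
#' @return integer matrix events x phenotype classes.
#' @export
recurrence_counts <- function(events, ped) {
  ped <- validate_pedigree(ped)
  validate_sv_members(events, ped)
  counts <- sapply(PHENO_CLASSES, function(cls) {
    ids <- members_of_class(ped, cls)
    if (length(ids) == 0L) return(rep(0L, nrow(events)))
    as.integer(rowSums(as.matrix(events[, ids, drop = FALSE]) != 0L))
  })
  matrix(as.integer(counts), nrow = nrow(events),
         dimnames = list(events$id, PHENO_CLASSES))
}

#' Screen SV events by per-group recurrence
#'
#' An event is retained when every group named in the rule's `min_rec`
#' meets its threshold (carrier count >= threshold) and, under control
#' exclusion, no excluded-group member carries it.
#'
#' @inheritParams recurrence_counts
#' @param rule a [recurrence_rule()].
#' @return list of class `"sv_screen"` with `retained` (event rows plus
#'   `rec_*` count columns and a `region_flag` column), `verdict` (logical
#'   per input event) and `counts` (the full recurrence-count matrix).
#' @examples
#' fx <- build_family_fixture()
#' scr <- screen_sv(fx$sv, fx$pedigree)
#' nrow(scr$retained)  # 2
#' @export
screen_sv <- function(events, ped, rule = recurrence_rule()) {
  stopifnot(inherits(rule, "recurrence_rule"))
  counts <- recurrence_counts(events, ped)
  verdict <- rep(TRUE, nrow(events))
  for (cls in names(rule$min_rec)) {
    verdict <- verdict & counts[, cls] >= rule$min_rec[[cls]]
  }
  if (rule$require_absent_in_excluded) {
    for (cls in rule$exclude_groups) {
      verdict <- verdict & counts[, cls] == 0L
    }
  }
  meta <- c("id", "type", "chrom1", "pos1", "chrom2", "pos2", "gene", "region_class")
  retained <- as.data.frame(events)[verdict, intersect(meta, names(events)), drop = FALSE]
  kept_counts <- counts[verdict, , drop = FALSE]
  for (cls in names(rule$min_rec)) {
    retained[[paste0("rec_", tolower(cls))]] <- kept_counts[, cls]
  }
  retained <- region_flag(retained)
  rownames(retained) <- NULL
  structure(list(retained = retained, verdict = verdict, counts = counts,
                 rule = rule), class = "sv_screen")
}

#' Flag events as exonic / non-exonic / unknown
#'
#' Pass-through annotation: candidates in exonic regions are separated from
#' non-exonic ones in the report rather than silently dropped. Events with
#' no region class are flagged `"unknown"` with a warning.
#'
#' @param events data.frame with a `region_class` column.
#' @return `events` with an added `region_flag` column.
#' @export
region_flag <- function(events) {
  rc <- if ("region_class" %in% names(events)) events$region_class else
    rep(NA_character_, nrow(events))
  flag <- ifelse(is.na(rc) | !nzchar(rc), "unknown",
                 ifelse(rc == "exonic", "exonic", "non_exonic"))
  if (any(flag == "unknown") && nrow(events) > 0) {
    warnf("%d event(s) lack a region class; flagged 'unknown'", sum(flag == "unknown"))
  }
  events$region_flag <- flag
  events
}

#' @method print sv_screen
#' @export
print.sv_screen <- function(x, ...) {
  cat(sprintf("<sv_screen> %d of %d event(s) retained\n",
              nrow(x$retained), length(x$verdict)))
  if (nrow(x$retained)) {
    print.data.frame(x$retained[, c("id", "gene", "region_flag",
                                    grep("^rec_", names(x$retained), value = TRUE))])
  }
  invisible(x)
}
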