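# I/O module: standard-format readers/writers and the joins that assemble
# the in-memory model (pedigree + genotype matrix + annotations + SV table).
# Coordinates are 1-based inclusive throughout, matching VCF.

#' Read a VCF into variants and a genotype matrix
#'
#' Parses a VCF (v4.x, plain or gzipped) with `vcfR` and returns one row
#' per biallelic site; multiallelic records are split into one row per ALT
#' allele, the genotype becoming the count of that specific allele. Sample
#' order is preserved. Missing genotypes (`./.`) stay `NA` — they are never
#' coerced to homozygous reference.
#'
#' @param path VCF file path.
#' @return list with `variants` (data.frame `chrom`, `pos`, `ref`, `alt`)
#'   and `genotypes` (integer matrix variants x samples, entries 0/1/2 or
#'   `NA`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stopf("failed to parse VCF %s: %s", path, conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stopf("VCF %s contains no variant records", path)
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stopf("VCF %s lacks a GT FORMAT field", path)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt_raw)

  out_var <- list(); out_gt <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt_raw[i, ], "[/|]")
    for (a in seq_along(alts)) {
      counts <- vapply(alleles, function(x) {
        if (length(x) == 0L || any(x == ".") || any(is.na(x))) return(NA_integer_)
        sum(x == as.character(a))
      }, integer(1))
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a], stringsAsFactors = FALSE)
      out_gt[[length(out_gt) + 1L]] <- counts
    }
  }
  variants <- do.call(rbind, out_var)
  gt <- do.call(rbind, out_gt)
  colnames(gt) <- samples
  rownames(gt) <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  storage.mode(gt) <- "integer"
  list(variants = variants, genotypes = gt)
}

#' Write variants + genotypes as a minimal VCF v4.2
#'
#' Emits a plain-text VCF with a GT-only FORMAT. Allele counts map to
#' diploid genotypes (0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param genotypes integer matrix (variants x samples).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path) {
  stopifnot(nrow(variants) == nrow(genotypes))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L], nrow = nrow(genotypes))
  gt_str[is.na(gt_str)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", ".", "GT", gt_str[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a PED-like pedigree file
#'
#' Expects a 6-column tab-separated file without header: family id,
#' member id, father id, mother id, sex, phenotype code. Parent id `0`
#' means absent; a non-zero parent id must resolve to another row.
#' Phenotype codes: 2 = MPLC, 1 = NODULE, 0 = UNAFFECTED, -9 = UNKNOWN.
#'
#' @param path PED file path.
#' @return a [pedigree()].
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stopf("PED file not found: %s", path)
  if (!any(nzchar(trimws(readLines(path))))) {
    stopf("PED file %s is empty: a pedigree needs at least one member", path)
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) < 6L) stopf("PED file %s has %d columns; 6 required", path, ncol(raw))
  names(raw)[1:6] <- c("fid", "id", "father_id", "mother_id", "sex", "code")
  dup <- raw$id[duplicated(raw$id)]
  if (length(dup)) stopf("duplicate member id '%s' in %s (row %d)",
                         dup[1], path, which(raw$id == dup[1])[2])
  code <- suppressWarnings(as.integer(raw$code))
  known <- match(code, PHENO_CODES)
  if (anyNA(known)) {
    bad <- which(is.na(known))[1]
    stopf("unknown phenotype code '%s' in %s (row %d)", raw$code[bad], path, bad)
  }
  for (col in c("father_id", "mother_id")) {
    p <- raw[[col]]
    missing_parent <- p %in% c("0", "", ".")
    unresolved <- !missing_parent & !(p %in% raw$id)
    if (any(unresolved)) {
      bad <- which(unresolved)[1]
      stopf("parent id '%s' does not resolve to any member in %s (row %d)",
            p[bad], path, bad)
    }
    raw[[col]][missing_parent] <- NA_character_
  }
  pedigree(id = raw$id, father_id = raw$father_id, mother_id = raw$mother_id,
           sex = suppressWarnings(as.integer(raw$sex)),
           phenotype = names(PHENO_CODES)[known])
}

#' Write a pedigree as a PED-like file
#' @param ped a [pedigree()].
#' @param path output path.
#' @param family_id family id written in column 1.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, family_id = "FAM1") {
  code <- PHENO_CODES[ped$phenotype]
  out <- data.frame(family_id, ped$id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    ifelse(is.na(ped$sex), 0L, ped$sex), code)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Join a variant list with an annotation table
#'
#' Annotations are keyed by `(chrom, pos, ref, alt)`. Matched variants get
#' their population-frequency fields, prediction calls, region class and
#' gene filled in; unmatched variants keep all annotation fields absent
#' (`NA`) — downstream, absent frequencies mean "novel", never frequency 0.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param annotation_table data.frame keyed by the same four columns with
#'   annotation columns `gene`, `af_*`, `sift_call`, `polyphen_call`,
#'   `region_class`.
#' @return data.frame of annotated variants (one row per input variant,
#'   order preserved).
#' @export
join_annotations <- function(variants, annotation_table) {
  ann_cols <- setdiff(names(annotation_table), c("chrom", "pos", "ref", "alt"))
  key_v <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  key_a <- variant_key(annotation_table$chrom, annotation_table$pos,
                       annotation_table$ref, annotation_table$alt)
  if (anyDuplicated(key_a)) {
    stopf("duplicate annotation key(s): %s",
          paste(unique(key_a[duplicated(key_a)])[1:3], collapse = ", "))
  }
  idx <- match(key_v, key_a)
  out <- variants
  for (col in ann_cols) out[[col]] <- annotation_table[[col]][idx]
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched > 0) {
    message(sprintf("join_annotations: %d of %d variants unannotated (treated as novel)",
                    n_unmatched, nrow(variants)))
  }
  out
}

#' Write a candidate report
#'
#' Serializes cascade or screen candidates as a TSV with a stable column
#' order and rows sorted by `(chrom, pos, ref, alt)` (or by event `id` for
#' SV candidates), so identical inputs produce byte-identical files.
#'
#' @param candidates data.frame of candidates (from [run_snv_cascade()] or
#'   [screen_sv()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path) {
  out <- as.data.frame(candidates)
  if (all(c("chrom", "pos") %in% names(out))) {
    out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  } else if ("id" %in% names(out)) {
    out <- out[order(out$id), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write candidate report to %s", path)
  invisible(path)
}

#' Read / write the variant annotation table
#' @param path TSV path with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `af_*`, `sift_call`, `polyphen_call`, `region_class`.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stopf("annotation table %s lacks column(s): %s",
                          path, paste(miss, collapse = ", "))
  ann
}

#' @rdname read_annotations
#' @param ann annotation data.frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a structural-variant event table
#'
#' Format: TSV with columns `id`, `type`, `chrom1`, `pos1`, `chrom2`,
#' `pos2`, `gene`, `region_class`, then one 0/1 presence column per
#' pedigree member id.
#'
#' @param path TSV path.
#' @return data.frame of class `"sv_table"`.
#' @export
read_sv_table <- function(path) {
  sv <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom1 = "character", chrom2 = "character"),
                          check.names = FALSE)
  need <- c("id", "type", "chrom1", "pos1", "chrom2", "pos2", "gene", "region_class")
  miss <- setdiff(need, names(sv))
  if (length(miss)) stopf("SV table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  bad_type <- setdiff(sv$type, SV_TYPES)
  if (length(bad_type)) stopf("SV table %s has unknown type(s): %s", path,
                              paste(bad_type, collapse = ", "))
  class(sv) <- c("sv_table", "data.frame")
  sv
}

#' @rdname read_sv_table
#' @param sv SV event data.frame.
#' @export
write_sv_table <- function(sv, path) {
  utils::write.table(sv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix (genes x samples TSV)
#' @param path TSV path: first column gene ids, remaining columns samples.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param expr numeric matrix, genes x samples.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("malformed GMT line (need name, description, >=1 gene): %s",
                              substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                        character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a limiting-dilution outcome table (CSV)
#' @param path CSV with columns `group`, `dose`, `n_tested`, `n_positive`.
#' @return validated data.frame.
#' @export
read_limiting_dilution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "dose", "n_tested", "n_positive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("limiting-dilution table %s lacks column(s): %s",
                          path, paste(miss, collapse = ", "))
  validate_ld_table(df)
  df
}

#' Read a qPCR Ct table (CSV)
#' @param path CSV with columns `sample`, `condition`, `target_ct`,
#'   `reference_ct`.
#' @return data.frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "target_ct", "reference_ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("qPCR table %s lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  if (!all(is.finite(df$target_ct)) || !all(is.finite(df$reference_ct))) {
    stopf("qPCR table %s has non-finite Ct values", path)
  }
  df
}

validate_sv_members <- function(sv, ped) {
  meta <- c("id", "type", "chrom1", "pos1", "chrom2", "pos2", "gene", "region_class")
  member_cols <- setdiff(names(sv), meta)
  if (!setequal(member_cols, ped$id)) {
    stopf("SV table member columns do not match the pedigree (missing: %s; extra: %s)",
          paste(setdiff(ped$id, member_cols), collapse = ","),
          paste(setdiff(member_cols, ped$id), collapse = ","))
  }
  invisible(member_cols)
}
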