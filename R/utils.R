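#' @keywords internal
"_PACKAGE"

# Phenotype classes used throughout; UNKNOWN members are never counted by
# any filter.
PHENO_CLASSES <- c("MPLC", "NODULE", "UNAFFECTED", "UNKNOWN")

# PED-file numeric phenotype coding.
PHENO_CODES <- c(MPLC = 2L, NODULE = 1L, UNAFFECTED = 0L, UNKNOWN = -9L)

SV_TYPES <- c("amplification", "deletion", "inversion", "translocation")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic generators in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic child seed derivation so each pipeline stage is reproducible
# independently of which other stages ran. Kept below 2^31.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100000L)) %% 2147483562L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
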