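---
title: "Pedigree variant prioritization and assay models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree variant prioritization and assay models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscreen)
```

## The problem

Multiple primary lung cancer (MPLC) — two or more independent primary lung
tumors in one patient — shows familial aggregation, suggesting dominant
germline susceptibility variants. Given whole-genome variant calls from a
small family in which five members have MPLC, nine have multiple pulmonary
nodules and one is unaffected, the task is to prioritize a candidate
variant by intersecting three kinds of evidence: the variant must be rare
in the relevant populations, it must co-segregate with disease under a
dominant model, and it must be predicted damaging. A parallel screen
applies a per-group recurrence threshold to structural-variant (SV)
events. Candidates are then validated in an independent proband cohort
(carrier frequency with an exact binomial interval), and their functional
consequences quantified with standard follow-up models: threshold
differential expression, gene-set enrichment, single-hit limiting-dilution
stem-cell frequency, relative qPCR expression and tumor volume.

`pedscreen` implements this whole workflow as composable R functions, with
a synthetic-data module that generates every input the pipeline consumes.

## The SNV cascade

Three pure set filters are intersected (order is irrelevant):

* **Frequency.** A variant passes when every *present* population allele
  frequency among the configured databases (`af_1kg_eas`, `af_esp`,
  `af_esp6500` by default) is strictly below `max_af` (default 0.01). A
  variant with no frequency record at all is *novel* and passes by
  default: absence of a database record is not evidence of commonness, and
  novel variants are exactly the ones a germline screen must keep. The
  threshold comparison is strict (`< 1%`), so an AF of exactly 0.01 fails.
* **Segregation.** Carrier means alt-allele count ≥ 1 (dominant model;
  homozygotes count). A variant passes when each required phenotype class
  reaches its minimum carrier count (defaults: 5 of 5 MPLC, 8 of 9 nodule)
  and at most `max_carriers_unaffected` (default 0) unaffected members
  carry it. The 8-of-9 default is a configurable tolerance for incomplete
  penetrance in the milder phenotype class, not a hard-coded family
  pattern. Missing genotypes are a distinct state: by default they count
  as non-carriers (conservative for a presence requirement, with a
  warning); `exclude_member` drops the member from that variant's tally
  instead.
* **Deleteriousness.** SIFT and PolyPhen categorical calls combine
  disjunctively by default (`either`); `both`, `sift_only` and
  `polyphen_only` are available. Whether the original analysis combined
  the two predictors conjunctively is not documented anywhere we could
  anchor it, so the disjunction is this package's own default, made
  explicit and configurable. Variants with neither call available are
  removed and counted in the stage log.

No multiple-testing correction applies: the cascade is deterministic
set-based filtering, not hypothesis testing.

The validation-cohort statistic is a binomial proportion with a
Clopper–Pearson exact interval (`stats::binom.test`). Percentage rendering
rounds half-up at one decimal, so 6/162 prints as 3.7.

## The SV recurrence screen

`rec` is the number of members of a phenotype group carrying an event —
the only reading under which thresholds of 5 and 9 are meaningful for
groups of exactly 5 and 9 members. The screen retains an event when every
thresholded group satisfies `rec ≥ min_rec` and, under control exclusion
(the default), no unaffected member carries it; a flag relaxes the
exclusion to merely ignoring the control group, since "excluding" a group
is ambiguous between the two. Retained events are flagged exonic /
non-exonic / unknown rather than filtered on region, so exonic candidates
stay visible in the report.

## Expression and enrichment

Differential expression is threshold-only: `log2fc` between two condition
means on the linear scale, called differential when `|log2fc| > 1`
strictly. The design this reproduces has single profiles per condition, so
no dispersion-based test is possible; this is a faithful reproduction of a
common three-condition overexpression design, not a recommendation. The
pseudocount added before the log defaults to 0 (suitable for strictly
positive intensities); count data should use e.g. 0.5. Cross-cell-line
intersection requires a gene to be differential in both lines, by default
with consistent sign.

Over-representation of curated sets in the shared differential list uses
the hypergeometric upper tail with the measured genes as universe — a
transparent stand-in for web-service annotation tools, with user-supplied
GMT collections.

The enrichment score is the classic running sum: walking the ranked
profile, in-set genes add `|stat|^p` normalized by total in-set mass,
out-of-set genes subtract `1/(N − |S|)`; ES is the signed maximum
deviation, bounded in [−1, 1] (checked against `fgsea::calcGseaStat` in
the test suite). Significance uses ES > 0.4 and permutation p < 0.05 at
1000 permutations. Permutations draw random same-size gene sets from the
profile (gene-label permutation): with one profile per condition,
phenotype permutation — the default of standalone GSEA software — is
impossible, and this deviation is deliberate and documented.

One calibration subtlety: the conventional sign-mirrored one-sided p
(upper tail for positive ES, lower for negative) is a reporting
convention, not a calibrated tail probability — under a null profile it
concentrates below 0.5 because each draw is referred to its own tail.
`gsea_permutation_p(alternative = "greater")` gives the fixed-direction
tail probability, which is uniform under the null and is what the
calibration tests check. The default (`"auto"`) keeps the conventional
mirrored definition used by the significance criteria.

## Single-hit limiting-dilution model

A limiting dilution assay implants graded cell doses and scores binary
tumor take. Under the single-hit Poisson model one active cell suffices,
so `P(positive | dose d) = 1 − exp(−f·d)` with `f` the active-cell
frequency. The binomial log-likelihood is maximized on `log f` (a scale on
which the problem is smooth and unconstrained); the optimum from a coarse
bounded search is polished to a score-equation root at tolerance 1e−13.
The 95% interval inverts the likelihood ratio (deviance 3.84, χ²₁),
solving each side to 1e−8 on `log f`; likelihood-ratio intervals track the
intervals of the standard ELDA web tool more closely than Wald intervals
at small n. Boundary tables are reported rather than refused: all-negative
gives `f_hat = 0` with a closed-form one-sided upper bound, all-positive
gives an infinite-MLE flag with a one-sided lower bound. Group comparison
fits shared vs per-group frequencies and refers twice the log-likelihood
difference to χ²₁, flagging the p-value approximate when any component
sits on a boundary.

The complementary log-log GLM with log-dose offset is the independent
oracle for the MLE in the test suite, never the implementation.

## ΔΔCt and tumor volume

`ΔCt = target − reference` per well (normalization to the endogenous
control, e.g. β-actin); technical replicates sharing a sample label are
averaged first (configurable), then per condition; `ΔΔCt` is taken
against the control condition and fold change is `2^−ΔΔCt`, pinning the
control at 1. Tumor volume is the ellipsoid approximation
`length × width² / 2`; width greater than length warns (axis convention)
but still computes.

## The synthetic-data module

The generators produce data with exactly the structure the analysis
assumes, so every pipeline claim can be tested against known truth:

* **Pedigree/genotypes.** A two-generation family: `n_founders` founder
  siblings, heterozygous for the planted variants, and children who
  inherit each planted allele with probability 1/2 (married-in parents
  assumed non-carriers). Background variants are independent per member at
  a Beta-distributed allele frequency — deliberately non-familial, since
  the segregation filter's job is precisely to separate transmitted from
  incidental variation. Phenotypes follow a penetrance matrix given
  carrier status of the first planted variant; the defaults (carrier →
  MPLC 0.35 / nodule 0.55 / unaffected 0.10; non-carrier → unaffected
  0.95) qualitatively reproduce a 13-of-15-carrier family with one
  nodule-class non-carrier. When exact per-class totals are requested,
  phenotypes are sampled *conditioned on those margins*, weighting each
  member by its penetrance row: unconditional penetrance draws and exact
  class counts cannot both hold, and conditioning preserves both the
  margins and the penetrance-driven association between carrier status
  and phenotype.
* **The deterministic fixture.** `build_family_fixture()` is a synthetic
  stand-in for a 15-member family study whose raw sequencing data are not
  publicly retrievable. It is built so the printed carrier patterns hold
  by construction: three rare-or-novel deleterious candidate SNVs carried
  by all 5 MPLC and 8 of 9 nodule members and absent from the unaffected
  member; 210 background variants each violating at least one cascade
  rule; two recurrent non-exonic SV events absent from the control; 24
  background SV events each under-recurrent or control-positive. The
  fixture is bit-identical across calls, uses synthetic gene labels, and
  leaves the identity of the non-carrier nodule member abstract
  (published descriptions of the source family disagree on which member
  was unaffected). Passing counts on this fixture demonstrate that the
  filters implement the stated rules, not that the rules would recover
  the same genes from the original data.
* **Expression.** Log2-scale baseline per gene (uniform on [4, 10]) plus
  planted condition effects plus Gaussian noise, exponentiated to the
  linear scale. Real RNA-seq has mean–variance dependence, library-size
  effects and correlated genes, none of which are modeled — the generator
  exists to verify effect recovery and enrichment calibration, not to
  benchmark normalization (which the pipeline deliberately does not
  perform; it accepts pre-normalized matrices).
* **Limiting dilution.** Direct Bernoulli sampling from the single-hit
  dose response, so estimator coverage can be measured against a known
  `f`.

All randomness flows from one seed per generator call through an
RNG-state-preserving wrapper; the pipeline's master seed fans out to
deterministic per-stage child seeds, so each stage is reproducible
independently of which other stages run.

## Problem sizes and numerical choices

The packaged test suite uses deliberately small designs: 15-member
pedigrees with tens to hundreds of variants, 30-variant brute-force oracle
comparisons, 400–2000-gene expression matrices, 500-replicate coverage
and calibration simulations, and 200-repetition permutation-uniformity
checks at 99 permutations — sizes at which exhaustive oracles are exact
and the whole suite runs in seconds, while leaving the binomial standard
errors tight enough for 3-sigma assertions. Tolerances: closed-form MLE
agreement at 1e−10 relative, interval inversion at 1e−8 on `log f`,
combinatorial-oracle agreement at 1e−12. Tie-breaking in ranked profiles
is alphabetical by gene label, making every ranking strictly ordered and
deterministic.

## Known limitations

Linkage analysis (LOD scores), kinship inference, phasing, variant
normalization, SV breakpoint merging across callers, expression
normalization and FDR across gene sets are all out of scope. The cascade
treats annotation fields as given; it neither computes predictor scores
nor resolves annotation dialects beyond the documented tables. The
single-hit model assumes independence across animals and exactly one
active cell sufficing; multi-hit or heterogeneity models are not
provided.
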