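#' Phenotype definition for ALT-based NAFLD classification
#'
#' A named, parameterized rule set: sex-specific case ALT thresholds (U/L),
#' sex-specific control ALT ceilings, the minimum gap and window (days) for
#' the qualifying elevated-ALT pair, and an optional metabolic risk-factor
#' requirement. The primary definition ("alt_threshold") requires ALT > 40
#' U/L for men and > 30 U/L for women at two time points at least 183 days
#' apart within a 730-day span, any time prior to enrollment; controls have
#' all ALT at or below 30 (men) / 20 (women) U/L. Alternative definitions
#' (lower cutoffs, required metabolic factors) are parameterizations of the
#' same class.
#'
#' @slot name definition label.
#' @slot caseThreshold named numeric, ALT case thresholds
#'   `c(male=, female=)` in U/L; values strictly above qualify.
#' @slot controlCeiling named numeric, ALT control ceilings `c(male=,
#'   female=)`; controls must have every pre-enrollment ALT at or below.
#' @slot minGapDays minimum days between the two qualifying elevations.
#' @slot windowDays maximum days between the two qualifying elevations.
#' @slot requiredFactors character vector of metabolic factors a case must
#'   carry, from `c("obesity","dyslipidemia","t2d","prediabetes",
#'   "hypertension")`; empty means no metabolic requirement.
#' @slot factorMode `"any"` (at least one of `requiredFactors`) or `"all"`.
#'
#' @seealso [phenotypeDefinition()], [nafldDefinitions()], [classifyCohort()]
#' @export
setClass("PhenotypeDefinition",
  representation(
    name = "character",
    caseThreshold = "numeric",
    controlCeiling = "numeric",
    minGapDays = "numeric",
    windowDays = "numeric",
    requiredFactors = "character",
    factorMode = "character"
  )
)

.metabolicFactorNames <- c(
  "obesity", "dyslipidemia", "t2d", "prediabetes", "hypertension"
)

setValidity("PhenotypeDefinition", function(object) {
  msg <- character()
  for (s in c("caseThreshold", "controlCeiling")) {
    v <- slot(object, s)
    if (!all(c("male", "female") %in% names(v)))
      msg <- c(msg, sprintf("%s must be named c(male=, female=)", s))
  }
  if (length(msg) == 0L) {
    if (any(object@caseThreshold[c("male", "female")] <
            object@controlCeiling[c("male", "female")]))
      msg <- c(msg, "case threshold must be >= control ceiling for each sex")
  }
  if (object@minGapDays > object@windowDays)
    msg <- c(msg, "minGapDays must be <= windowDays")
  if (object@minGapDays < 0) msg <- c(msg, "minGapDays must be >= 0")
  bad <- setdiff(object@requiredFactors, .metabolicFactorNames)
  if (length(bad))
    msg <- c(msg, paste("unknown metabolic factor(s):",
                        paste(bad, collapse = ", ")))
  if (!object@factorMode %in% c("any", "all"))
    msg <- c(msg, "factorMode must be 'any' or 'all'")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhenotypeDefinition display thresholds and requirements
#' @param object a `PhenotypeDefinition`
#' @export
setMethod("show", "PhenotypeDefinition", function(object) {
  cat("PhenotypeDefinition:", object@name, "\n")
  cat(sprintf("  case ALT > %g (M) / %g (F) U/L, two values %g-%g days apart\n",
              object@caseThreshold["male"], object@caseThreshold["female"],
              object@minGapDays, object@windowDays))
  cat(sprintf("  control ALT <= %g (M) / %g (F) U/L\n",
              object@controlCeiling["male"], object@controlCeiling["female"]))
  if (length(object@requiredFactors))
    cat("  required metabolic factor(s) [", object@factorMode, "]: ",
        paste(object@requiredFactors, collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

#' Synthetic EHR cohort container
#'
#' Holds the five EHR-shaped tables emitted by the generator (participants,
#' longitudinal labs, diagnosis codes, medication records) together with the
#' genotype dosages (a [SummarizedExperiment::SummarizedExperiment] with
#' variants as rows), the planted ground truth, and the simulation
#' configuration (including the seed) for reproducibility.
#'
#' @slot participants data.frame: id, sex, age_at_enrollment, ancestry,
#'   PC1..PC10, audit_c.
#' @slot labs data.frame: id, analyte, value, day, hour (hour is NA except
#'   for draws that carry a time of day, e.g. triglycerides).
#' @slot codes data.frame: id, system (ICD9/ICD10), code, day.
#' @slot meds data.frame: id, drug_class, day.
#' @slot genotypes SummarizedExperiment, assay "dosage" (variants x
#'   participants in [0,2]), rowData = variant annotations.
#' @slot truth data.frame of planted status, metabolic flags and expected
#'   stratum per participant.
#' @slot config list, the `simConfig()` used.
#'
#' @seealso [simulateCohort()], [participants()], [labs()], [codes()],
#'   [meds()], [genotypes()], [cohortTruth()]
#' @export
setClass("SyntheticCohort",
  representation(
    participants = "data.frame",
    labs = "data.frame",
    codes = "data.frame",
    meds = "data.frame",
    genotypes = "SummarizedExperiment",
    truth = "data.frame",
    config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- object@participants$id
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate participant ids")
  if (ncol(object@genotypes) != length(ids))
    msg <- c(msg, "genotype columns must match participant count")
  d <- SummarizedExperiment::assay(object@genotypes, "dosage")
  if (length(d) && (min(d) < 0 || max(d) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticCohort summary of tables and planted truth
#' @param object a `SyntheticCohort`
#' @export
setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@participants), "participants,",
      nrow(object@genotypes), "variants\n")
  cat("  labs:", nrow(object@labs), "rows; codes:", nrow(object@codes),
      "; meds:", nrow(object@meds), "\n")
  if (nrow(object@truth)) {
    tab <- table(object@truth$expected_stratum)
    cat("  planted strata:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  cat("  seed:", object@config$seed, "\n")
  invisible(NULL)
})
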