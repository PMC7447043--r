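#' Construct a phenotype definition
#'
#' @param name definition label.
#' @param caseThreshold named numeric `c(male=, female=)`, ALT U/L; values
#'   strictly above count toward the qualifying pair.
#' @param controlCeiling named numeric `c(male=, female=)`, ALT U/L; controls
#'   must have every pre-enrollment ALT at or below this ceiling.
#' @param minGapDays,windowDays the qualifying pair must be separated by at
#'   least `minGapDays` and at most `windowDays` days (defaults 183 / 730,
#'   i.e. six months and two years).
#' @param requiredFactors metabolic factors required of a case (character,
#'   possibly empty), from `c("obesity","dyslipidemia","t2d","prediabetes",
#'   "hypertension")`.
#' @param factorMode `"any"` or `"all"` of `requiredFactors`.
#' @return a [PhenotypeDefinition-class] object.
#' @examples
#' phenotypeDefinition("alt_threshold")
#' @export
phenotypeDefinition <- function(name = "alt_threshold",
                                caseThreshold = c(male = 40, female = 30),
                                controlCeiling = c(male = 30, female = 20),
                                minGapDays = 183,
                                windowDays = 730,
                                requiredFactors = character(),
                                factorMode = "any") {
  new("PhenotypeDefinition",
      name = name,
      caseThreshold = caseThreshold,
      controlCeiling = controlCeiling,
      minGapDays = as.numeric(minGapDays),
      windowDays = as.numeric(windowDays),
      requiredFactors = requiredFactors,
      factorMode = factorMode)
}

#' Standard NAFLD phenotype definitions
#'
#' The primary ALT-threshold definition (case ALT > 40 M / > 30 F, control
#' ALT <= 30 M / <= 20 F), the lower-cutoff ABALT variant, the metabolic
#' definition requiring at least one of obesity, dyslipidemia, T2D or
#' prediabetes, and the sensitivity definitions that each require one
#' specific metabolic factor. All are plain parameterizations of
#' [phenotypeDefinition()] and can be edited.
#'
#' @return named list of [PhenotypeDefinition-class] objects.
#' @examples
#' names(nafldDefinitions())
#' @export
nafldDefinitions <- function() {
  base <- phenotypeDefinition("alt_threshold")
  anyMet <- c("obesity", "dyslipidemia", "t2d", "prediabetes")
  list(
    alt_threshold = base,
    abalt = phenotypeDefinition("abalt",
      caseThreshold = c(male = 30, female = 20),
      controlCeiling = c(male = 30, female = 20)),
    alt_metabolic = phenotypeDefinition("alt_metabolic",
      requiredFactors = anyMet),
    abalt2 = phenotypeDefinition("abalt2",
      caseThreshold = c(male = 30, female = 20),
      controlCeiling = c(male = 30, female = 20),
      requiredFactors = anyMet),
    alt2dl = phenotypeDefinition("alt2dl",
      requiredFactors = "dyslipidemia"),
    alt2dm = phenotypeDefinition("alt2dm",
      requiredFactors = "t2d"),
    alt2htn = phenotypeDefinition("alt2htn",
      requiredFactors = "hypertension"),
    alt2obese = phenotypeDefinition("alt2obese",
      requiredFactors = "obesity")
  )
}
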