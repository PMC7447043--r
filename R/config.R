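#' Default exclusionary diagnosis-code patterns
#'
#' Prefix patterns (dot-stripped, case-folded) for the liver-disease and
#' alcohol-use-disorder diagnoses that exclude a participant from both the
#' case and control strata: alcohol-related liver disease / alcohol use
#' disorder, chronic viral hepatitis, hereditary/metabolic liver disease,
#' cholestatic liver disease, and liver metastases. These stand in for the
#' full institutional code lists and are meant to be edited to the local
#' coding practice.
#'
#' @return named list of character vectors of code prefixes; names are the
#'   exclusion reason categories.
#' @examples
#' names(defaultExclusionPatterns())
#' @export
defaultExclusionPatterns <- function() {
  list(
    alcohol_related = c("5710", "5711", "5712", "5713", "303", "3050",
                        "K70", "F10"),
    viral_hepatitis = c("0702", "0703", "0704", "0705", "B16", "B17",
                        "B18", "B19"),
    metabolic_hereditary = c("2750", "2751", "2754", "E831", "E830", "E880"),
    cholestatic = c("5716", "5761", "K743", "K744", "K745", "K830"),
    liver_metastasis = c("1977", "C787")
  )
}

#' Default risk-factor and diabetes-pattern code patterns
#'
#' Editable prefix lists backing the metabolic risk-factor rules:
#' hypertension (ICD-9 401.x-405.x / ICD-10 I10-I16), dyslipidemia (272.x /
#' E78.0-E78.5), type 2 diabetes codes, prediabetes codes (790.2x except
#' 790.29; R73.xx except R73.03), their exceptions, and diabetic
#' ketoacidosis codes used by the type-1-pattern exclusion.
#'
#' @return named list of character vectors of code prefixes (`*_except`
#'   entries are prefixes that negate a match of the same category).
#' @export
defaultCodePatterns <- function() {
  list(
    hypertension = c("401", "402", "403", "404", "405",
                     "I10", "I11", "I12", "I13", "I15", "I16"),
    dyslipidemia = c("272", "E780", "E781", "E782", "E783", "E784", "E785"),
    t2d = c("250", "E11"),
    prediabetes = c("7902", "R73"),
    prediabetes_except = c("79029", "R7303"),
    dka = c("2501", "E101", "E111")
  )
}

#' Synthetic cohort simulation configuration
#'
#' Defaults emulate the study conditions of a large, predominantly male
#' veteran biobank: ancestry mix ~73/20/7 (EU/AA/LA), age 64.5 +/- 13.1
#' years, 8.4% female, case prevalence 0.31 among analytic participants,
#' ~22% of participants carrying an exclusionary liver-disease code and
#' ~23% of the remainder with maximum ALT in the intermediate band.
#' Metabolic risk-factor rates are conditional on case status (cases carry
#' more obesity, dyslipidemia, T2D and hypertension). AUDIT-C is drawn
#' Binomial(12, 0.22) so roughly a third of men exceed the misuse cutoff.
#'
#' @param n total participants; split across ancestries by `ancestryMix`.
#' @param targetPrevalence case fraction among non-excluded,
#'   non-indeterminate participants, in (0,1).
#' @param exclusionFraction fraction of participants planted with an
#'   exclusionary liver-disease/alcohol code.
#' @param indeterminateFraction fraction (of non-excluded) planted with
#'   maximum ALT in the intermediate band.
#' @param ancestryMix named non-negative weights over ancestries.
#' @param ageMean,ageSD age at enrollment (years).
#' @param fractionFemale fraction of female participants.
#' @param auditCProb per-item success probability of the Binomial(12, p)
#'   AUDIT-C score.
#' @param metabolicRates list with `case` and `control` named rate vectors
#'   for obesity, dyslipidemia, hypertension, t2d, prediabetes.
#' @param altPerParticipant expected number of ALT measurements beyond the
#'   required minimum of two.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return list of class `"simConfig"`.
#' @examples
#' cfg <- simConfig(n = 500, seed = 7)
#' @export
simConfig <- function(n = 5000,
                      targetPrevalence = 0.31,
                      exclusionFraction = 0.22,
                      indeterminateFraction = 0.233,
                      ancestryMix = c(EU = 0.728, AA = 0.202, LA = 0.070),
                      ageMean = 64.5, ageSD = 13.1,
                      fractionFemale = 0.084,
                      auditCProb = 0.22,
                      metabolicRates = list(
                        case = c(obesity = 0.573, dyslipidemia = 0.677,
                                 hypertension = 0.816, t2d = 0.350,
                                 prediabetes = 0.334),
                        control = c(obesity = 0.408, dyslipidemia = 0.430,
                                    hypertension = 0.662, t2d = 0.218,
                                    prediabetes = 0.396)
                      ),
                      altPerParticipant = 2,
                      seed = 1L) {
  stopifnot(n > 0, targetPrevalence > 0, targetPrevalence < 1,
            exclusionFraction >= 0, exclusionFraction < 1,
            indeterminateFraction >= 0, indeterminateFraction < 1,
            all(ancestryMix >= 0), sum(ancestryMix) > 0,
            fractionFemale >= 0, fractionFemale <= 1)
  cfg <- list(n = as.integer(n), targetPrevalence = targetPrevalence,
              exclusionFraction = exclusionFraction,
              indeterminateFraction = indeterminateFraction,
              ancestryMix = ancestryMix / sum(ancestryMix),
              ageMean = ageMean, ageSD = ageSD,
              fractionFemale = fractionFemale,
              auditCProb = auditCProb,
              metabolicRates = metabolicRates,
              altPerParticipant = altPerParticipant,
              seed = as.integer(seed))
  class(cfg) <- c("simConfig", "list")
  cfg
}

# deterministic per-stage sub-seed, kept below 2^31
.stageSeed <- function(seed, stage) {
  offsets <- c(genotypes = 101L, status = 211L, metabolic = 307L,
               labs = 401L, codes = 503L, adjudication = 601L,
               covariates = 701L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
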