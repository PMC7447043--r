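#' @title ALT rule primitives
#' @description Helpers implementing the temporal ALT criteria: the
#'   qualifying elevated pair and the windowed maximum.
#' @name alt-rules
NULL

#' @describeIn alt-rules TRUE iff two measurements both strictly above
#'   `threshold` exist whose days differ by at least `minGapDays` and at
#'   most `windowDays`. Days are integers relative to enrollment (day 0);
#'   all must be `<= 0`.
#' @param values numeric ALT values (U/L).
#' @param days integer days relative to enrollment (<= 0).
#' @param threshold sex-specific case threshold (U/L), exceeded strictly.
#' @param minGapDays,windowDays pair separation bounds in days.
#' @examples
#' qualifyingAltPair(c(45, 45), c(-400, -200), threshold = 40)  # TRUE
#' qualifyingAltPair(c(45, 45), c(-900, -100), threshold = 40)  # FALSE
#' @export
qualifyingAltPair <- function(values, days, threshold,
                              minGapDays = 183, windowDays = 730) {
  stopifnot(length(values) == length(days))
  if (!length(values)) return(FALSE)
  if (any(days > 0)) stop("all days must be <= 0 (prior to enrollment)")
  d <- sort(days[values > threshold])
  .pairInWindow(d, minGapDays, windowDays)
}

.pairInWindow <- function(sortedDays, minGapDays, windowDays) {
  k <- length(sortedDays)
  if (k < 2L) return(FALSE)
  for (i in seq_len(k - 1L)) {
    gaps <- sortedDays[(i + 1L):k] - sortedDays[i]
    if (any(gaps >= minGapDays & gaps <= windowDays)) return(TRUE)
  }
  FALSE
}

#' @describeIn alt-rules maximum ALT with `-windowDays <= day <= 0`
#'   (the two years before enrollment); `NA` if no measurement falls in the
#'   window.
#' @export
altMax <- function(values, days, windowDays = 730) {
  stopifnot(length(values) == length(days))
  keep <- days <= 0 & days >= -windowDays
  if (!any(keep)) return(NA_real_)
  max(values[keep])
}

# dot-stripped, case-folded diagnosis codes for prefix matching
.normalizeCode <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

.matchesAny <- function(code, prefixes) {
  norm <- .normalizeCode(code)
  pref <- .normalizeCode(prefixes)
  m <- rep(FALSE, length(norm))
  for (p in pref) m <- m | startsWith(norm, p)
  m
}

#' Exclusionary-code screen
#'
#' Prefix-matches a participant's diagnosis codes against the exclusion
#' configuration (codes and patterns are dot-stripped and case-folded).
#' The reason is the first matching category in the order of `patterns`.
#'
#' @param codes character vector of diagnosis codes for one participant
#'   (or a data.frame with a `code` column).
#' @param patterns named list of prefix vectors, see
#'   [defaultExclusionPatterns()].
#' @return list with `excluded` (flag) and `reason` (category name or
#'   `NA`).
#' @examples
#' hasExclusion("571.2")$reason
#' hasExclusion("I10")$excluded
#' @export
hasExclusion <- function(codes, patterns = defaultExclusionPatterns()) {
  if (is.data.frame(codes)) codes <- codes$code
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))) ||
      !all(vapply(patterns, is.character, TRUE)))
    stop("exclusion patterns must be a named list of character prefixes")
  if (!length(codes)) return(list(excluded = FALSE, reason = NA_character_))
  for (cat in names(patterns)) {
    if (any(.matchesAny(codes, patterns[[cat]])))
      return(list(excluded = TRUE, reason = cat))
  }
  list(excluded = FALSE, reason = NA_character_)
}

#' AUDIT-C alcohol-misuse flag
#'
#' Standard VA screening cutoffs: score >= 4 for men, >= 3 for women.
#'
#' @param score integer AUDIT-C score(s) in 0-12.
#' @param sex `"male"`/`"female"`, recycled against `score`.
#' @return logical vector.
#' @examples
#' auditCMisuse(4, "male")
#' auditCMisuse(2, "female")
#' @export
auditCMisuse <- function(score, sex) {
  if (any(is.na(score)) || any(score < 0 | score > 12))
    stop("AUDIT-C score must lie in [0, 12]")
  ifelse(sex == "male", score >= 4, score >= 3)
}

# most recent pre-enrollment observation per id for one analyte;
# returns data.table id/value(/hour)
.mostRecent <- function(labsDt, what) {
  x <- labsDt[analyte == what & day <= 0]
  if (!nrow(x))
    return(data.table::data.table(id = character(), value = numeric(),
                                  hour = numeric()))
  data.table::setorder(x, id, day)
  x[, utils::tail(.SD, 1L), by = id][, c("id", "value", "hour"), with = FALSE]
}

#' Derive metabolic risk-factor flags
#'
#' Applies the risk-factor rules to the most recent pre-enrollment
#' observation per analyte:
#' obesity is BMI >= 30 kg/m^2; dyslipidemia is triglycerides >= 150 mg/dL
#' drawn before 9 AM, or HDL < 40 (men) / < 50 (women) mg/dL with at least
#' two dyslipidemia codes, or any fibrate prescription (a statin alone
#' never qualifies); hypertension is any 401.x-405.x / I10-I16 code; T2D is
#' a qualifying diagnosis code without a type-1-like pattern (insulin with
#' no oral agent, onset age < 40, BMI < 25, or a ketoacidosis code), or
#' HbA1c >= 6.5%, or glucose >= 200 mg/dL, or diabetes prescriptions on at
#' least two distinct days; prediabetes is a qualifying code or HbA1c in
#' [5.7, 6.49] in the absence of diabetes. Missing analytes yield `FALSE`,
#' never errors. Triglyceride draws without a time stamp never satisfy the
#' before-9AM criterion.
#'
#' @param labsDf long lab table (`id`, `analyte`, `value`, `day`, optional
#'   `hour`).
#' @param codesDf diagnosis codes (`id`, `system`, `code`, `day`).
#' @param medsDf medication records (`id`, `drug_class`, `day`).
#' @param participantsDf participant table with `id`, `sex`,
#'   `age_at_enrollment`.
#' @param codePatterns see [defaultCodePatterns()].
#' @return data.frame keyed by `id` with logical columns `obesity`,
#'   `dyslipidemia`, `hypertension`, `t2d`, `prediabetes`, `any_metabolic`
#'   (obesity | dyslipidemia | t2d | prediabetes; hypertension is tracked
#'   but not counted toward the metabolic case requirement).
#' @export
metabolicFlags <- function(labsDf, codesDf, medsDf, participantsDf,
                           codePatterns = defaultCodePatterns()) {
  ids <- participantsDf$id
  labsDt <- data.table::as.data.table(labsDf)
  if (!"hour" %in% names(labsDt)) labsDt[, hour := NA_real_]
  codesDt <- data.table::as.data.table(codesDf)
  medsDt <- data.table::as.data.table(medsDf)

  val <- function(what) {
    r <- .mostRecent(labsDt, what)
    r$value[match(ids, r$id)]
  }
  bmi <- val("bmi"); hba1c <- val("hba1c"); glucose <- val("glucose")
  hdl <- val("hdl")
  tgRec <- .mostRecent(labsDt, "tg")
  tg <- tgRec$value[match(ids, tgRec$id)]
  tgHour <- tgRec$hour[match(ids, tgRec$id)]

  countMatch <- function(prefixes, except = NULL) {
    if (!nrow(codesDt)) return(integer(length(ids)))
    m <- .matchesAny(codesDt$code, prefixes)
    if (!is.null(except)) m <- m & !.matchesAny(codesDt$code, except)
    tab <- codesDt[m, .N, by = id]
    out <- tab$N[match(ids, tab$id)]
    ifelse(is.na(out), 0L, out)
  }
  htnN <- countMatch(codePatterns$hypertension)
  dlN <- countMatch(codePatterns$dyslipidemia)
  t2dN <- countMatch(codePatterns$t2d)
  preN <- countMatch(codePatterns$prediabetes,
                     except = codePatterns$prediabetes_except)
  dkaN <- countMatch(codePatterns$dka)

  # earliest diabetes evidence (code or qualifying lab) for onset age
  onsetDay <- rep(NA_real_, length(ids))
  if (nrow(codesDt)) {
    m <- .matchesAny(codesDt$code, codePatterns$t2d)
    if (any(m)) {
      e <- codesDt[m, .(d = min(day)), by = id]
      onsetDay <- e$d[match(ids, e$id)]
    }
  }
  qlab <- labsDt[(analyte == "hba1c" & value >= 6.5) |
                 (analyte == "glucose" & value >= 200)]
  if (nrow(qlab)) {
    e <- qlab[, .(d = min(day)), by = id]
    onsetDay <- pmin(onsetDay, e$d[match(ids, e$id)], na.rm = TRUE)
  }
  age <- participantsDf$age_at_enrollment
  onsetAge <- age + onsetDay / 365.25

  medFlag <- function(classes) {
    if (!nrow(medsDt)) return(rep(FALSE, length(ids)))
    tab <- medsDt[drug_class %in% classes, .N, by = id]
    ids %in% tab$id
  }
  dmMedDays <- {
    if (!nrow(medsDt)) integer(length(ids)) else {
      tab <- medsDt[drug_class %in% c("diabetes_oral", "insulin"),
                    .(nd = length(unique(day))), by = id]
      out <- tab$nd[match(ids, tab$id)]
      ifelse(is.na(out), 0L, out)
    }
  }
  insulin <- medFlag("insulin")
  oral <- medFlag("diabetes_oral")
  fibrate <- medFlag("fibrate")

  obesity <- !is.na(bmi) & bmi >= 30
  hdlCut <- ifelse(participantsDf$sex == "male", 40, 50)
  dl <- (!is.na(tg) & tg >= 150 & !is.na(tgHour) & tgHour < 9) |
        (!is.na(hdl) & hdl < hdlCut & dlN >= 2L) |
        fibrate
  hypertension <- htnN >= 1L

  t1dPattern <- (insulin & !oral) |
    (!is.na(onsetAge) & onsetAge < 40) |
    (!is.na(bmi) & bmi < 25) |
    dkaN >= 1L
  t2d <- (t2dN >= 1L & !t1dPattern) |
    (!is.na(hba1c) & hba1c >= 6.5) |
    (!is.na(glucose) & glucose >= 200) |
    dmMedDays >= 2L
  prediabetes <- (preN >= 1L |
                  (!is.na(hba1c) & hba1c >= 5.7 & hba1c <= 6.49)) & !t2d

  data.frame(id = ids, obesity = obesity, dyslipidemia = dl,
             hypertension = hypertension, t2d = t2d,
             prediabetes = prediabetes,
             any_metabolic = obesity | dl | t2d | prediabetes,
             stringsAsFactors = FALSE)
}

#' Classify participants under a phenotype definition
#'
#' Applies the full rule set to each participant: excluded when any
#' diagnosis code matches the exclusion configuration; otherwise case when
#' a qualifying elevated-ALT pair exists (and, for metabolic definitions,
#' the required factor is present); otherwise control when at least one
#' pre-enrollment ALT exists and all are at or below the control ceiling;
#' otherwise indeterminate. Participants with a qualifying pair but without
#' the required metabolic factor are indeterminate, not controls.
#'
#' @param participantsDf participant table (`id`, `sex`,
#'   `age_at_enrollment`, ...); missing sex is a classification error.
#' @param labsDf,codesDf,medsDf the EHR-shaped tables (see
#'   [metabolicFlags()]).
#' @param definition a [PhenotypeDefinition-class].
#' @param exclusionPatterns see [defaultExclusionPatterns()].
#' @param codePatterns see [defaultCodePatterns()].
#' @return data.frame: `id`, `phenotype`, `stratum` (case / control /
#'   indeterminate / excluded), `reason`, `alt_max` (maximum ALT in the
#'   2-year window, NA if none), plus the metabolic flag columns.
#' @examples
#' sc <- simulateCohort(simConfig(n = 120, seed = 3))
#' calls <- classifyCohort(participants(sc), labs(sc), codes(sc), meds(sc))
#' table(calls$stratum)
#' @export
classifyCohort <- function(participantsDf, labsDf, codesDf, medsDf,
                           definition = phenotypeDefinition(),
                           exclusionPatterns = defaultExclusionPatterns(),
                           codePatterns = defaultCodePatterns()) {
  if (anyDuplicated(participantsDf$id))
    stop("duplicate participant ids")
  if (any(is.na(participantsDf$sex)) ||
      !all(participantsDf$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female' for every participant")
  ids <- participantsDf$id
  n <- length(ids)
  thr <- ifelse(participantsDf$sex == "male",
                definition@caseThreshold["male"],
                definition@caseThreshold["female"])
  ceil <- ifelse(participantsDf$sex == "male",
                 definition@controlCeiling["male"],
                 definition@controlCeiling["female"])

  labsDt <- data.table::as.data.table(labsDf)
  altDt <- labsDt[analyte == "alt" & day <= 0]
  altDt <- altDt[id %in% ids]
  thrById <- stats::setNames(thr, ids)
  gmin <- definition@minGapDays; gmax <- definition@windowDays
  altSum <- if (nrow(altDt) == 0L) {
    data.table::data.table(id = character(), n_alt = integer(),
                           alt_max_win = numeric(), max_all = numeric(),
                           pair = logical())
  } else altDt[, .(
    n_alt = .N,
    alt_max_win = {
      k <- day >= -gmax
      if (any(k)) max(value[k]) else NA_real_
    },
    max_all = max(value),
    pair = .pairInWindow(sort(day[value > thrById[[id[1L]]]]), gmin, gmax)
  ), by = id]
  nAlt <- altSum$n_alt[match(ids, altSum$id)]
  nAlt[is.na(nAlt)] <- 0L
  altMaxWin <- altSum$alt_max_win[match(ids, altSum$id)]
  maxAll <- altSum$max_all[match(ids, altSum$id)]
  hasPair <- altSum$pair[match(ids, altSum$id)]
  hasPair[is.na(hasPair)] <- FALSE

  # exclusion screen: first matching category in pattern order
  excluded <- rep(FALSE, n)
  excReason <- rep(NA_character_, n)
  codesDt <- data.table::as.data.table(codesDf)
  if (nrow(codesDt)) {
    catIdx <- rep(NA_integer_, nrow(codesDt))
    for (k in rev(seq_along(exclusionPatterns)))
      catIdx[.matchesAny(codesDt$code, exclusionPatterns[[k]])] <- k
    hit <- codesDt[!is.na(catIdx)]
    hit$catIdx <- catIdx[!is.na(catIdx)]
    if (nrow(hit)) {
      first <- hit[, .(k = min(catIdx)), by = id]
      mm <- match(ids, first$id)
      excluded <- !is.na(mm)
      excReason[excluded] <-
        names(exclusionPatterns)[first$k[mm[excluded]]]
    }
  }

  met <- metabolicFlags(labsDf, codesDf, medsDf, participantsDf,
                        codePatterns)
  met <- met[match(ids, met$id), ]
  metOK <- if (!length(definition@requiredFactors)) rep(TRUE, n) else {
    cols <- lapply(definition@requiredFactors, function(f) met[[f]])
    m <- do.call(cbind, cols)
    if (definition@factorMode == "any") rowSums(m) > 0 else
      rowSums(m) == ncol(m)
  }

  stratum <- rep("indeterminate", n)
  reason <- rep(NA_character_, n)
  isControl <- nAlt > 0L & !is.na(maxAll) & maxAll <= ceil
  stratum[isControl] <- "control"
  caseRule <- hasPair & metOK
  stratum[caseRule] <- "case"
  noMet <- hasPair & !metOK
  stratum[noMet] <- "indeterminate"
  reason[noMet] <- "no required metabolic factor"
  reason[stratum == "indeterminate" & nAlt == 0L] <- "no ALT"
  reason[stratum == "indeterminate" & is.na(reason)] <- "intermediate ALT"
  stratum[excluded] <- "excluded"
  reason[excluded] <- excReason[excluded]

  out <- data.frame(id = ids, phenotype = definition@name,
                    stratum = stratum, reason = reason,
                    alt_max = altMaxWin, stringsAsFactors = FALSE)
  cbind(out, met[, setdiff(names(met), "id"), drop = FALSE])
}

# half-up decimal rounding (matches printed table percentages)
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Stratum accounting for a set of phenotype calls
#'
#' Exact stratum sums and the case percentages among all classified and
#' among the analytic (case + control) subset, rounded half-up to the
#' requested precision.
#'
#' @param calls data.frame from [classifyCohort()] (one row per
#'   participant; duplicate ids are an error).
#' @param digits decimal places for percentages.
#' @return data.frame of counts and percentages.
#' @export
cohortAccounting <- function(calls, digits = 1) {
  if (anyDuplicated(calls$id)) stop("duplicate participant ids")
  n <- nrow(calls)
  cnt <- function(s) sum(calls$stratum == s)
  cases <- cnt("case"); controls <- cnt("control")
  analytic <- cases + controls
  pct <- function(num, den) if (den > 0)
    roundHalfUp(100 * num / den, digits) else NA_real_
  data.frame(
    metric = c("total", "excluded", "indeterminate", "analytic", "cases",
               "controls", "pct_case_of_total", "pct_case_of_analytic"),
    value = c(n, cnt("excluded"), cnt("indeterminate"), analytic, cases,
              controls, pct(cases, n), pct(cases, analytic)),
    stringsAsFactors = FALSE
  )
}

#' Cohort-flow arithmetic from printed stage counts
#'
#' Recomputes the eligibility flow of an ALT-based NAFLD cohort from its
#' component counts: the eligible total across ancestries, the exclusion
#' total across reason groups, the analytic cohort (eligible minus excluded
#' minus intermediate-ALT), the metabolic-definition cohort (metabolic
#' cases plus the shared controls), and the case percentages.
#'
#' @param eligibleByAncestry named counts of eligible participants.
#' @param exclusions named counts of excluded participants by reason.
#' @param intermediate count removed for intermediate ALT values.
#' @param cases case count under the primary definition.
#' @param metabolicCases case count under the metabolic definition.
#' @return named list: `eligible_total`, `excluded_total`,
#'   `analytic_total`, `controls`, `metabolic_total`,
#'   `pct_case_of_eligible` (whole percent), `pct_case_of_analytic` (whole
#'   percent), `pct_metabolic_of_cases` (one decimal).
#' @examples
#' flow <- cohortFlow()
#' flow$analytic_total
#' @export
cohortFlow <- function(eligibleByAncestry = c(EU = 234683, AA = 64961,
                                              LA = 22615),
                       exclusions = c(alcohol_related = 51549,
                                      viral_hepatitis = 7995,
                                      other_liver = 11468),
                       intermediate = 58631,
                       cases = 60542,
                       metabolicCases = 58964) {
  eligible <- sum(eligibleByAncestry)
  excl <- sum(exclusions)
  analytic <- eligible - excl - intermediate
  controls <- analytic - cases
  list(
    eligible_total = eligible,
    excluded_total = excl,
    analytic_total = analytic,
    controls = controls,
    metabolic_total = metabolicCases + controls,
    pct_case_of_eligible = roundHalfUp(100 * cases / eligible, 0),
    pct_case_of_analytic = roundHalfUp(100 * cases / analytic, 0),
    pct_metabolic_of_cases = roundHalfUp(100 * metabolicCases / cases, 1)
  )
}
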