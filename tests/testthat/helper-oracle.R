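# Independent brute-force references. Everything here is re-derived from
# first principles with plain loops so the package implementation can be
# checked against it; nothing below calls package internals.

oracleNormCode <- function(code) toupper(gsub(".", "", code, fixed = TRUE))

oracleCodeMatch <- function(code, prefixes, except = character()) {
  nc <- oracleNormCode(code)
  hit <- FALSE
  for (p in oracleNormCode(prefixes))
    if (substr(nc, 1, nchar(p)) == p) hit <- TRUE
  if (hit) for (p in oracleNormCode(except))
    if (substr(nc, 1, nchar(p)) == p) hit <- FALSE
  hit
}

# enumerate every pair of measurements
oracleQualifyingPair <- function(values, days, threshold,
                                 minGap = 183, window = 730) {
  k <- length(values)
  if (k < 2) return(FALSE)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (values[i] > threshold && values[j] > threshold) {
      gap <- abs(days[j] - days[i])
      if (gap >= minGap && gap <= window) return(TRUE)
    }
  }
  FALSE
}

oracleAltMax <- function(values, days, window = 730) {
  best <- NA_real_
  for (i in seq_along(values))
    if (days[i] <= 0 && days[i] >= -window)
      if (is.na(best) || values[i] > best) best <- values[i]
  best
}

# most recent pre-enrollment observation of one analyte; list(value, hour)
oracleRecent <- function(labsOne, what) {
  rows <- labsOne[labsOne$analyte == what & labsOne$day <= 0, , drop = FALSE]
  if (nrow(rows) == 0) return(list(value = NA_real_, hour = NA_real_))
  rows <- rows[order(rows$day), , drop = FALSE]
  last <- rows[nrow(rows), ]
  list(value = last$value,
       hour = if ("hour" %in% names(rows)) last$hour else NA_real_)
}

# re-derive the metabolic profile for one participant from scratch
oracleMetabolic <- function(labsOne, codesOne, medsOne, sex, age) {
  pats <- defaultCodePatterns()
  bmi <- oracleRecent(labsOne, "bmi")$value
  hba1c <- oracleRecent(labsOne, "hba1c")$value
  glucose <- oracleRecent(labsOne, "glucose")$value
  hdl <- oracleRecent(labsOne, "hdl")$value
  tgr <- oracleRecent(labsOne, "tg")

  nMatch <- function(prefixes, except = character()) {
    n <- 0
    for (cd in codesOne$code)
      if (oracleCodeMatch(cd, prefixes, except)) n <- n + 1
    n
  }
  medAny <- function(cls) any(medsOne$drug_class %in% cls)
  dmDays <- length(unique(
    medsOne$day[medsOne$drug_class %in% c("diabetes_oral", "insulin")]))

  obesity <- !is.na(bmi) && bmi >= 30
  hdlCut <- if (sex == "male") 40 else 50
  dl <- (!is.na(tgr$value) && tgr$value >= 150 &&
           !is.na(tgr$hour) && tgr$hour < 9) ||
    (!is.na(hdl) && hdl < hdlCut && nMatch(pats$dyslipidemia) >= 2) ||
    medAny("fibrate")
  htn <- nMatch(pats$hypertension) >= 1

  onset <- Inf
  for (i in seq_len(nrow(codesOne)))
    if (oracleCodeMatch(codesOne$code[i], pats$t2d))
      onset <- min(onset, codesOne$day[i])
  for (i in seq_len(nrow(labsOne))) {
    qual <- (labsOne$analyte[i] == "hba1c" && labsOne$value[i] >= 6.5) ||
      (labsOne$analyte[i] == "glucose" && labsOne$value[i] >= 200)
    if (qual) onset <- min(onset, labsOne$day[i])
  }
  t1dPattern <- (medAny("insulin") && !medAny("diabetes_oral")) ||
    (is.finite(onset) && age + onset / 365.25 < 40) ||
    (!is.na(bmi) && bmi < 25) ||
    nMatch(pats$dka) >= 1
  t2d <- (nMatch(pats$t2d) >= 1 && !t1dPattern) ||
    (!is.na(hba1c) && hba1c >= 6.5) ||
    (!is.na(glucose) && glucose >= 200) ||
    dmDays >= 2
  prediab <- (nMatch(pats$prediabetes, pats$prediabetes_except) >= 1 ||
                (!is.na(hba1c) && hba1c >= 5.7 && hba1c <= 6.49)) && !t2d
  list(obesity = obesity, dyslipidemia = dl, hypertension = htn,
       t2d = t2d, prediabetes = prediab,
       any_metabolic = obesity || dl || t2d || prediab)
}

# full single-participant classification from first principles
oracleClassify <- function(labsOne, codesOne, medsOne, sex, age,
                           definition = phenotypeDefinition()) {
  for (cat in names(defaultExclusionPatterns())) {
    pats <- defaultExclusionPatterns()[[cat]]
    for (cd in codesOne$code)
      if (oracleCodeMatch(cd, pats)) return("excluded")
  }
  altRows <- labsOne[labsOne$analyte == "alt" & labsOne$day <= 0, ,
                     drop = FALSE]
  thr <- definition@caseThreshold[[sex]]
  ceil <- definition@controlCeiling[[sex]]
  pair <- oracleQualifyingPair(altRows$value, altRows$day, thr,
                               definition@minGapDays, definition@windowDays)
  met <- oracleMetabolic(labsOne, codesOne, medsOne, sex, age)
  req <- definition@requiredFactors
  metOK <- if (length(req) == 0) TRUE else {
    hits <- vapply(req, function(f) isTRUE(met[[f]]), TRUE)
    if (definition@factorMode == "any") any(hits) else all(hits)
  }
  if (pair && metOK) return("case")
  if (pair && !metOK) return("indeterminate")
  if (nrow(altRows) > 0 && all(altRows$value <= ceil)) return("control")
  "indeterminate"
}

# literal re-evaluations of the fibrosis formulas
oracleFib4 <- function(age, ast, alt, platelets)
  (age * ast) / (platelets * sqrt(alt))
oracleNfs <- function(age, bmi, diab, ast, alt, platelets, albumin)
  -1.675 + (0.037 * age) + (0.094 * bmi) + (1.13 * diab) +
  (0.99 * (ast / alt)) - (0.013 * platelets) - (0.66 * albumin)
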