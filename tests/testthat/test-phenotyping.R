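test_that("qualifying ALT pair honors the gap and window bounds", {
  expect_true(qualifyingAltPair(c(45, 45), c(-400, -200), threshold = 40))
  expect_false(qualifyingAltPair(numeric(), integer(), threshold = 40))
  # gap of 800 days exceeds the two-year window
  expect_false(qualifyingAltPair(c(45, 45), c(-900, -100), threshold = 40))
  # second value not above threshold
  expect_false(qualifyingAltPair(c(41, 39), c(-300, -100), threshold = 40))
  # threshold is strict
  expect_false(qualifyingAltPair(c(40, 40), c(-400, -200), threshold = 40))
  # gap exactly at the bounds qualifies
  expect_true(qualifyingAltPair(c(45, 45), c(-383, -200), threshold = 40))
  expect_true(qualifyingAltPair(c(45, 45), c(-730, 0), threshold = 40))
  expect_error(qualifyingAltPair(c(45, 45), c(-100, 10), threshold = 40),
               "<= 0")
})

test_that("windowed ALT maximum", {
  expect_equal(altMax(c(20, 35, 28), c(-100, -300, -600)), 35)
  expect_true(is.na(altMax(50, -800)))
  expect_true(is.na(altMax(numeric(), integer())))
  # values outside the window are invisible to the maximum
  expect_equal(altMax(c(99, 20), c(-800, -10)), 20)
})

test_that("exclusion screen prefix-matches dot-stripped codes", {
  expect_true(hasExclusion("571.2")$excluded)
  expect_equal(hasExclusion("571.2")$reason, "alcohol_related")
  expect_false(hasExclusion(character())$excluded)
  # hypertension is a covariate, not an exclusion
  expect_false(hasExclusion("I10")$excluded)
  expect_true(hasExclusion(c("I10", "b18.2"))$excluded)
  expect_equal(hasExclusion(c("I10", "b18.2"))$reason, "viral_hepatitis")
  expect_error(hasExclusion("571.2", patterns = list(c("5712"))),
               "named list")
})

test_that("dyslipidemia rule: TG timing, HDL+codes, fibrate, statin", {
  p <- oneParticipant("male")
  tgEarly <- labRows("p1", "tg", 160, -30, hour = 8.5)
  tgLate <- labRows("p1", "tg", 160, -30, hour = 10)
  expect_true(metabolicFlags(tgEarly, codeRows(), medRows(),
                             p)$dyslipidemia)
  expect_false(metabolicFlags(tgLate, codeRows(), medRows(),
                              p)$dyslipidemia)
  # a TG draw without a time stamp never qualifies
  tgNoHour <- labRows("p1", "tg", 160, -30)
  expect_false(metabolicFlags(tgNoHour, codeRows(), medRows(),
                              p)$dyslipidemia)

  # low HDL needs two dyslipidemia codes
  hdl <- labRows("p1", "hdl", 35, -30)
  twoCodes <- codeRows(c("p1", "p1"), c("ICD9", "ICD10"),
                       c("272.4", "E78.5"), c(-100L, -50L))
  oneCode <- twoCodes[1, ]
  expect_true(metabolicFlags(hdl, twoCodes, medRows(), p)$dyslipidemia)
  expect_false(metabolicFlags(hdl, oneCode, medRows(), p)$dyslipidemia)
  # female cutoff is 50: HDL 45 qualifies for women, not men
  pf <- oneParticipant("female")
  hdl45 <- labRows("p1", "hdl", 45, -30)
  expect_true(metabolicFlags(hdl45, twoCodes, medRows(), pf)$dyslipidemia)
  expect_false(metabolicFlags(hdl45, twoCodes, medRows(), p)$dyslipidemia)

  expect_true(metabolicFlags(noLabs(), codeRows(),
                             medRows("p1", "fibrate", -10L),
                             p)$dyslipidemia)
  # statin alone never implies dyslipidemia
  expect_false(metabolicFlags(noLabs(), codeRows(),
                              medRows("p1", "statin", -10L),
                              p)$dyslipidemia)
})

test_that("dysglycemia rules: HbA1c bands, prescriptions, T1D pattern", {
  p <- oneParticipant("male", age = 60)
  m <- metabolicFlags(labRows("p1", "hba1c", 6.0, -30), codeRows(),
                      medRows(), p)
  expect_true(m$prediabetes); expect_false(m$t2d)
  m <- metabolicFlags(labRows("p1", "hba1c", 6.7, -30), codeRows(),
                      medRows(), p)
  expect_true(m$t2d); expect_false(m$prediabetes)
  expect_true(metabolicFlags(labRows("p1", "glucose", 210, -30),
                             codeRows(), medRows(), p)$t2d)

  # two prescriptions on distinct days qualify; same day does not
  two <- medRows(c("p1", "p1"), "diabetes_oral", c(-10L, -100L))
  same <- medRows(c("p1", "p1"), "diabetes_oral", c(-10L, -10L))
  expect_true(metabolicFlags(noLabs(), codeRows(), two, p)$t2d)
  expect_false(metabolicFlags(noLabs(), codeRows(), same, p)$t2d)

  # T2D code stands, unless a type-1-like pattern negates it
  t2dCode <- codeRows("p1", "ICD10", "E11.9", -200L)
  expect_true(metabolicFlags(noLabs(), t2dCode, medRows(), p)$t2d)
  insOnly <- medRows("p1", "insulin", -50L)
  expect_false(metabolicFlags(noLabs(), t2dCode, insOnly, p)$t2d)
  lean <- labRows("p1", "bmi", 23, -30)
  expect_false(metabolicFlags(lean, t2dCode, medRows(), p)$t2d)
  dka <- rbind(t2dCode, codeRows("p1", "ICD9", "250.1", -300L))
  expect_false(metabolicFlags(noLabs(), dka, medRows(), p)$t2d)
  # onset before age 40: code 25 years before enrollment at age 60
  early <- codeRows("p1", "ICD10", "E11.9", as.integer(-25 * 365.25))
  expect_false(metabolicFlags(noLabs(), early, medRows(), p)$t2d)

  # prediabetes code exceptions
  preCode <- codeRows("p1", "ICD10", "R73.09", -100L)
  exCode <- codeRows("p1", "ICD10", "R73.03", -100L)
  expect_true(metabolicFlags(noLabs(), preCode, medRows(), p)$prediabetes)
  expect_false(metabolicFlags(noLabs(), exCode, medRows(), p)$prediabetes)
})

test_that("obesity uses the most recent pre-enrollment BMI", {
  p <- oneParticipant("male")
  hist <- rbind(labRows("p1", "bmi", 33, -500), labRows("p1", "bmi", 28, -20))
  expect_false(metabolicFlags(hist, codeRows(), medRows(), p)$obesity)
  expect_true(metabolicFlags(hist[1, ], codeRows(), medRows(), p)$obesity)
  # missing analytes yield FALSE, never errors
  m <- metabolicFlags(noLabs(), codeRows(), medRows(), p)
  expect_false(any(unlist(m[, -1])))
})

test_that("classification covers case, control, indeterminate, excluded", {
  def <- phenotypeDefinition()
  p <- oneParticipant("male")
  caseLabs <- labRows(c("p1", "p1"), "alt", c(45, 45), c(-400L, -200L))
  calls <- classifyCohort(p, caseLabs, codeRows(), medRows(), def)
  expect_equal(calls$stratum, "case")
  expect_equal(calls$alt_max, 45)

  ctrl <- labRows(c("p1", "p1"), "alt", c(23, 18), c(-300L, -50L))
  expect_equal(classifyCohort(p, ctrl, codeRows(), medRows(),
                              def)$stratum, "control")

  mid <- labRows("p1", "alt", 35, -100L)
  ind <- classifyCohort(p, mid, codeRows(), medRows(), def)
  expect_equal(ind$stratum, "indeterminate")
  expect_equal(ind$reason, "intermediate ALT")

  pf <- oneParticipant("female")
  viral <- codeRows("p1", "ICD10", "B18.2", -400L)
  fLabs <- labRows(c("p1", "p1"), "alt", c(35, 40), c(-400L, -200L))
  exc <- classifyCohort(pf, fLabs, viral, medRows(), def)
  expect_equal(exc$stratum, "excluded")
  expect_equal(exc$reason, "viral_hepatitis")

  none <- classifyCohort(p, noLabs(), codeRows(), medRows(), def)
  expect_equal(none$stratum, "indeterminate")
  expect_equal(none$reason, "no ALT")

  pNA <- oneParticipant("male"); pNA$sex <- NA_character_
  expect_error(classifyCohort(pNA, caseLabs, codeRows(), medRows(), def),
               "sex")
})

test_that("metabolic-mode definitions demote factor-free cases", {
  def <- nafldDefinitions()$alt_metabolic
  p <- oneParticipant("male")
  caseLabs <- labRows(c("p1", "p1"), "alt", c(45, 45), c(-400L, -200L))
  noMet <- classifyCohort(p, caseLabs, codeRows(), medRows(), def)
  expect_equal(noMet$stratum, "indeterminate")
  expect_equal(noMet$reason, "no required metabolic factor")

  withBmi <- rbind(caseLabs, labRows("p1", "bmi", 32, -30))
  expect_equal(classifyCohort(p, withBmi, codeRows(), medRows(),
                              def)$stratum, "case")
  # hypertension alone does not satisfy the metabolic requirement
  htn <- codeRows("p1", "ICD10", "I10", -100L)
  expect_equal(classifyCohort(p, caseLabs, htn, medRows(), def)$stratum,
               "indeterminate")
  # but a definition that names hypertension specifically accepts it
  expect_equal(classifyCohort(p, caseLabs, htn, medRows(),
                              nafldDefinitions()$alt2htn)$stratum, "case")
})

test_that("AUDIT-C misuse cutoffs are sex-specific", {
  expect_true(auditCMisuse(4, "male"))
  expect_false(auditCMisuse(3, "male"))
  expect_true(auditCMisuse(3, "female"))
  expect_false(auditCMisuse(2, "female"))
  expect_false(auditCMisuse(0, "male"))
  expect_error(auditCMisuse(13, "male"), "\\[0, 12\\]")
  expect_error(auditCMisuse(-1, "female"), "\\[0, 12\\]")
})

test_that("every participant receives exactly one stratum", {
  for (seed in c(101, 202)) {
    mini <- randomMiniCohort(60, seed)
    calls <- classifyCohort(mini$participants, mini$labs, mini$codes,
                            mini$meds)
    expect_equal(nrow(calls), nrow(mini$participants))
    expect_equal(anyDuplicated(calls$id), 0L)
    expect_true(all(calls$stratum %in%
                      c("case", "control", "indeterminate", "excluded")))
  }
})

test_that("raising the case threshold never increases the case count", {
  mini <- randomMiniCohort(80, 303)
  counts <- vapply(c(30, 40, 50, 60), function(thr) {
    def <- phenotypeDefinition(caseThreshold = c(male = thr,
                                                 female = thr - 10),
                               controlCeiling = c(male = 20, female = 15))
    sum(classifyCohort(mini$participants, mini$labs, mini$codes,
                       mini$meds, def)$stratum == "case")
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("definition nesting: stricter definitions select subsets", {
  mini <- randomMiniCohort(80, 404)
  defs <- nafldDefinitions()
  strat <- function(d) classifyCohort(mini$participants, mini$labs,
                                      mini$codes, mini$meds, d)
  altCases <- strat(defs$alt_threshold)
  abaltCases <- strat(defs$abalt)
  metCases <- strat(defs$alt_metabolic)
  inAlt <- altCases$id[altCases$stratum == "case"]
  inAbalt <- abaltCases$id[abaltCases$stratum == "case"]
  inMet <- metCases$id[metCases$stratum == "case"]
  expect_true(all(inAlt %in% inAbalt))
  expect_true(all(inMet %in% inAlt))
})

test_that("brute-force oracle agrees with the classifier", {
  for (def in list(phenotypeDefinition(),
                   nafldDefinitions()$alt_metabolic)) {
    cmp <- compareToOracle(randomMiniCohort(50, 999), def)
    expect_identical(cmp$called, cmp$oracle)
  }
})

test_that("stratum accounting sums exactly and rejects duplicates", {
  mini <- randomMiniCohort(40, 505)
  calls <- classifyCohort(mini$participants, mini$labs, mini$codes,
                          mini$meds)
  acc <- cohortAccounting(calls)
  g <- function(m) acc$value[acc$metric == m]
  expect_equal(g("total"), 40)
  expect_equal(g("analytic"), g("cases") + g("controls"))
  expect_equal(g("total"),
               g("analytic") + g("excluded") + g("indeterminate"))
  expect_error(cohortAccounting(rbind(calls, calls[1, ])), "duplicate")
  empty <- cohortAccounting(calls[0, ])
  expect_true(all(empty$value[empty$metric %in%
    c("total", "cases", "controls")] == 0))
})

test_that("cohort-flow arithmetic reproduces printed identities", {
  flow <- cohortFlow()
  expect_equal(flow$eligible_total, 322259)
  expect_equal(flow$excluded_total, 71012)
  expect_equal(flow$analytic_total, 192616)
  expect_equal(flow$controls, 132074)
  expect_equal(flow$metabolic_total, 191038)
  expect_equal(flow$pct_case_of_eligible, 19)
  expect_equal(flow$pct_case_of_analytic, 31)
  expect_equal(flow$pct_metabolic_of_cases, 97.4)
})
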