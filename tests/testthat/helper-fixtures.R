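# Small in-code fixtures for unit tests.

# one-participant bundle builder
oneParticipant <- function(sex = "male", age = 60, id = "p1") {
  data.frame(id = id, sex = sex, age_at_enrollment = age,
             ancestry = "EU",
             matrix(0, 1, 10, dimnames = list(NULL, paste0("PC", 1:10))),
             audit_c = 0L, stringsAsFactors = FALSE)
}

labRows <- function(id, analyte, value, day, hour = NA_real_) {
  if (length(id) == 0) return(noLabs())
  data.frame(id = id, analyte = analyte, value = value, day = day,
             hour = hour, stringsAsFactors = FALSE)
}

noLabs <- function() {
  data.frame(id = character(), analyte = character(), value = numeric(),
             day = integer(), hour = numeric(), stringsAsFactors = FALSE)
}

codeRows <- function(id = character(), system = character(),
                     code = character(), day = integer()) {
  data.frame(id = id, system = system, code = code, day = day,
             stringsAsFactors = FALSE)
}

medRows <- function(id = character(), drug_class = character(),
                    day = integer()) {
  data.frame(id = id, drug_class = drug_class, day = day,
             stringsAsFactors = FALSE)
}

# random mini-cohort with raw, rule-agnostic records: exercises every
# branch of the classifier against the brute-force oracle
randomMiniCohort <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("m%04d", seq_len(n))
  parts <- data.frame(
    id = ids,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_at_enrollment = runif(n, 25, 90),
    ancestry = "EU",
    matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10))),
    audit_c = sample(0:12, n, replace = TRUE),
    stringsAsFactors = FALSE)

  codePool <- c("571.2", "K70.30", "B18.2", "070.54", "275.0", "571.6",
                "197.7", "401.9", "I10", "272.4", "E78.5", "250.00",
                "E11.9", "790.21", "R73.09", "R73.03", "790.29", "2501",
                "V70.0", "Z00.0", "J18.9")
  medPool <- c("fibrate", "statin", "diabetes_oral", "insulin", "other")
  labsL <- list(); codesL <- list(); medsL <- list()
  for (i in seq_len(n)) {
    nAlt <- sample(0:5, 1)
    rows <- list()
    if (nAlt > 0)
      rows$alt <- labRows(ids[i], "alt", runif(nAlt, 5, 90),
                          -sample.int(1000L, nAlt))
    for (an in c("ast", "platelets", "albumin", "bmi", "hba1c", "glucose",
                 "hdl")) {
      if (runif(1) < 0.75) {
        v <- switch(an, ast = runif(1, 10, 120),
                    platelets = runif(1, 60, 450),
                    albumin = runif(1, 2.5, 5.2), bmi = runif(1, 17, 45),
                    hba1c = runif(1, 4.5, 9.5), glucose = runif(1, 60, 260),
                    hdl = runif(1, 20, 90))
        rows[[an]] <- labRows(ids[i], an, v, -sample.int(400L, 1))
      }
    }
    if (runif(1) < 0.75)
      rows$tg <- labRows(ids[i], "tg", runif(1, 60, 400),
                         -sample.int(400L, 1), hour = runif(1, 5, 14))
    labsL[[i]] <- do.call(rbind, rows)
    nC <- stats::rpois(1, 1.5)
    if (nC > 0)
      codesL[[i]] <- codeRows(rep(ids[i], nC), "mixed",
                              sample(codePool, nC, replace = TRUE),
                              -sample.int(1500L, nC, replace = TRUE))
    nM <- stats::rpois(1, 1)
    if (nM > 0)
      medsL[[i]] <- medRows(rep(ids[i], nM),
                            sample(medPool, nM, replace = TRUE),
                            -sample.int(900L, nM, replace = TRUE))
  }
  list(participants = parts,
       labs = {
         x <- do.call(rbind, labsL)
         if (is.null(x)) noLabs() else x
       },
       codes = {
         x <- do.call(rbind, codesL)
         if (is.null(x)) codeRows() else x
       },
       meds = {
         x <- do.call(rbind, medsL)
         if (is.null(x)) medRows() else x
       })
}

# per-participant comparison of classifyCohort against the oracle
compareToOracle <- function(mini, definition = phenotypeDefinition()) {
  calls <- classifyCohort(mini$participants, mini$labs, mini$codes,
                          mini$meds, definition = definition)
  expect_setequal(calls$id, mini$participants$id)
  oracle <- vapply(seq_len(nrow(mini$participants)), function(i) {
    id <- mini$participants$id[i]
    oracleClassify(
      mini$labs[mini$labs$id == id, , drop = FALSE],
      mini$codes[mini$codes$id == id, , drop = FALSE],
      mini$meds[mini$meds$id == id, , drop = FALSE],
      mini$participants$sex[i], mini$participants$age_at_enrollment[i],
      definition = definition)
  }, "")
  data.frame(id = mini$participants$id,
             called = calls$stratum[match(mini$participants$id, calls$id)],
             oracle = oracle, stringsAsFactors = FALSE)
}
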