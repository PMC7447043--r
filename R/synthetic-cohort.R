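#' Sample Hardy-Weinberg genotype dosages
#'
#' Draws per-participant allele dosages at each variant as Binomial(2, EAF)
#' under Hardy-Weinberg equilibrium, with no linkage disequilibrium between
#' variants. Ancestry-specific frequencies are taken from an `eaf_<ancestry>`
#' column when present, otherwise from `eaf`; a variant with no usable
#' frequency for the requested ancestry is a configuration error.
#'
#' @param variants variant annotation data.frame (see [nafldVariantPanel()]).
#' @param n number of participants.
#' @param ancestry ancestry label (e.g. `"EU"`).
#' @param seed integer seed.
#' @param ids optional participant ids (length `n`).
#' @return [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"dosage"` (variants x participants, values in 0:2), `rowData` carrying
#'   the variant annotations and `colData` the ancestry.
#' @examples
#' se <- sampleGenotypes(nafldVariantPanel(), n = 10, seed = 1)
#' dim(se)
#' @export
sampleGenotypes <- function(variants, n, ancestry = "EU", seed = 1L,
                            ids = NULL) {
  .checkVariantPanel(variants)
  ancCol <- paste0("eaf_", ancestry)
  eaf <- if (ancCol %in% names(variants)) variants[[ancCol]] else variants$eaf
  if (is.null(eaf) || any(is.na(eaf)))
    stop("no effect-allele frequency available for ancestry '", ancestry, "'")
  k <- nrow(variants)
  set.seed(seed)
  dos <- matrix(stats::rbinom(n * k, size = 2L, prob = rep(eaf, times = n)),
                nrow = k, ncol = n)
  if (is.null(ids)) ids <- sprintf("%s_%05d", ancestry, seq_len(n))
  dimnames(dos) <- list(variants$rsid, ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dos),
    rowData = S4Vectors::DataFrame(variants, row.names = variants$rsid),
    colData = S4Vectors::DataFrame(ancestry = rep(ancestry, n),
                                   row.names = ids)
  )
}

#' Plant case/control status from genotypes
#'
#' Draws each participant's case status from a logistic model
#' \eqn{P(\mathrm{case}) = \mathrm{logit}^{-1}(\alpha + \sum_j d_j \beta_j +
#' x'\gamma)} where \eqn{d_j} is the dosage at variant j and \eqn{\beta_j}
#' its planted additive log-odds effect. When `intercept` is `NULL`, the
#' intercept \eqn{\alpha} is solved numerically so the expected marginal
#' prevalence equals `targetPrevalence` for this cohort's realized dosages.
#'
#' @param genotypes a `SummarizedExperiment` from [sampleGenotypes()] (or a
#'   variants x participants dosage matrix, in which case `beta` must be
#'   given).
#' @param beta per-variant planted log-odds effects; defaults to the `beta`
#'   column of `rowData(genotypes)`.
#' @param covariates optional numeric matrix/data.frame (participants x
#'   covariates) entering the linear predictor.
#' @param covariateBeta log-odds effects for `covariates` (default zero:
#'   pure genotype planting).
#' @param targetPrevalence marginal case fraction in (0,1).
#' @param intercept fixed log-odds intercept; overrides the calibration.
#' @param seed integer seed.
#' @return data.frame with `id`, `prob` (planted case probability) and
#'   `status` (`"case"`/`"control"`); the calibrated intercept is attached
#'   as attribute `"intercept"`.
#' @examples
#' se <- sampleGenotypes(nafldVariantPanel(), n = 200, seed = 1)
#' st <- assignCaseStatus(se, targetPrevalence = 0.31, seed = 2)
#' table(st$status)
#' @export
assignCaseStatus <- function(genotypes, beta = NULL, covariates = NULL,
                             covariateBeta = NULL, targetPrevalence = 0.31,
                             intercept = NULL, seed = 1L) {
  if (methods::is(genotypes, "SummarizedExperiment")) {
    dos <- SummarizedExperiment::assay(genotypes, "dosage")
    if (is.null(beta)) beta <- SummarizedExperiment::rowData(genotypes)$beta
  } else {
    dos <- as.matrix(genotypes)
  }
  if (is.null(beta)) stop("planted beta must be supplied")
  if (length(beta) != nrow(dos))
    stop("beta length must equal the number of variants")
  if (!all(is.finite(beta))) stop("planted beta must be finite")
  eta <- as.numeric(crossprod(dos, beta))
  if (!is.null(covariates)) {
    x <- as.matrix(covariates)
    if (is.null(covariateBeta)) covariateBeta <- rep(0, ncol(x))
    eta <- eta + as.numeric(x %*% covariateBeta)
  }
  if (is.null(intercept)) {
    stopifnot(targetPrevalence > 0, targetPrevalence < 1)
    f <- function(a) mean(stats::plogis(a + eta)) - targetPrevalence
    intercept <- stats::uniroot(f, lower = -30, upper = 30,
                                tol = 1e-10)$root
  }
  p <- stats::plogis(intercept + eta)
  set.seed(seed)
  status <- ifelse(stats::rbinom(length(p), 1L, p) == 1L, "case", "control")
  ids <- colnames(dos)
  if (is.null(ids)) ids <- sprintf("S_%05d", seq_along(p))
  out <- data.frame(id = ids, prob = p, status = status,
                    stringsAsFactors = FALSE)
  attr(out, "intercept") <- intercept
  out
}

# case/control conditional metabolic truth + dyslipidemia mechanism
.planMetabolicTruth <- function(status, rates, seed) {
  set.seed(seed)
  n <- length(status)
  pick <- function(factor) {
    p <- ifelse(status == "case", rates$case[[factor]],
                rates$control[[factor]])
    stats::rbinom(n, 1L, p) == 1L
  }
  out <- data.frame(
    obesity = pick("obesity"),
    dyslipidemia = pick("dyslipidemia"),
    hypertension = pick("hypertension"),
    t2d = pick("t2d"),
    prediabetes = pick("prediabetes")
  )
  # prediabetes is defined in the absence of diabetes
  out$prediabetes <- out$prediabetes & !out$t2d
  mech <- rep("none", n)
  dl <- which(out$dyslipidemia)
  mech[dl] <- sample(c("tg", "hdl_codes", "fibrate"), length(dl),
                     replace = TRUE, prob = c(0.5, 0.3, 0.2))
  out$dl_mechanism <- mech
  out
}

#' Emit longitudinal lab series consistent with planted labels
#'
#' Inverse design of the classification rules: planted cases receive two
#' ALT values above their sex-specific case threshold separated by 183-730
#' days before enrollment; planted controls receive only ALT values at or
#' below their control ceiling; participants planted as indeterminate get a
#' maximum ALT in the intermediate band (no qualifying pair possible).
#' AST is emitted alongside each ALT draw; platelets, albumin, BMI, HbA1c,
#' glucose, triglycerides (with a draw hour) and HDL are emitted once per
#' participant with values consistent with the planted metabolic flags
#' (e.g. HbA1c >= 6.5 for planted T2D, in [5.7, 6.49] for prediabetes).
#'
#' @param truth data.frame with columns `id`, `sex`, `status`,
#'   `indeterminate`, `excluded`, plus the metabolic flag columns from the
#'   planner (`obesity`, `t2d`, `prediabetes`, `dl_mechanism`).
#' @param config a [simConfig()] list.
#' @param seed integer seed.
#' @param definition the [PhenotypeDefinition-class] whose thresholds the
#'   series are built against (default the primary ALT-threshold rule).
#' @return long data.frame: `id`, `analyte`, `value`, `day`, `hour`.
#' @export
emitLabSeries <- function(truth, config, seed = 1L,
                          definition = phenotypeDefinition()) {
  set.seed(seed)
  n <- nrow(truth)
  thr <- ifelse(truth$sex == "male",
                definition@caseThreshold["male"],
                definition@caseThreshold["female"])
  ceil <- ifelse(truth$sex == "male",
                 definition@controlCeiling["male"],
                 definition@controlCeiling["female"])
  gapMin <- definition@minGapDays
  gapMax <- definition@windowDays

  # ALT profile: indeterminate overrides the planted case/control profile
  profile <- ifelse(truth$indeterminate, "indeterminate", truth$status)

  pieces <- vector("list", 4L)

  # qualifying pair for case-profile participants
  isCase <- profile == "case"
  nc <- sum(isCase)
  if (nc) {
    day1 <- -round(runif(nc, gapMin, gapMax))
    gap <- round(runif(nc, gapMin, pmin(gapMax, -day1)))
    day2 <- day1 + gap
    v1 <- thr[isCase] * runif(nc, 1.10, 2.2)
    v2 <- thr[isCase] * runif(nc, 1.10, 2.2)
    pieces[[1L]] <- data.frame(
      id = rep(truth$id[isCase], 2L),
      value = c(v1, v2), day = c(day1, day2))
  }

  # indeterminate band maximum: one value in (ceiling, threshold]
  isInd <- profile == "indeterminate"
  ni <- sum(isInd)
  if (ni) {
    vmax <- ceil[isInd] + runif(ni, 0.3, 1) * (thr[isInd] - ceil[isInd])
    pieces[[2L]] <- data.frame(id = truth$id[isInd], value = vmax,
                               day = -round(runif(ni, 0, gapMax)))
  }

  # remaining ALT draws: capped at the profile's allowed maximum
  nExtra <- stats::rpois(n, config$altPerParticipant) +
    ifelse(isCase | isInd, 0L, 2L)  # controls need >= 1 measurement
  capPer <- ifelse(isCase, thr, ceil)  # indeterminate handled below
  capPer[isInd] <- ceil[isInd]         # extras stay below the planted max
  idx <- rep(seq_len(n), nExtra)
  if (length(idx)) {
    pieces[[3L]] <- data.frame(
      id = truth$id[idx],
      value = runif(length(idx), 8, pmax(capPer[idx], 9)),
      day = -round(runif(length(idx), 0, gapMax)))
  }
  alt <- data.table::rbindlist(pieces[!vapply(pieces, is.null, TRUE)])
  alt[, `:=`(analyte = "alt", hour = NA_real_)]

  # AST alongside each ALT draw (correlated, typically a bit lower)
  ast <- data.frame(id = alt$id, analyte = "ast",
                    value = alt$value * runif(nrow(alt), 0.6, 1.05),
                    day = alt$day, hour = NA_real_)

  one <- function(analyte, value, hour = NA_real_) {
    data.frame(id = truth$id, analyte = analyte, value = value,
               day = -round(runif(n, 0, 365)), hour = hour)
  }
  platelets <- one("platelets", pmin(pmax(rnorm(n, 243, 58), 60), 480))
  albumin <- one("albumin", pmin(pmax(rnorm(n, 4.1, 0.35), 2.6), 5.2))
  bmi <- one("bmi", ifelse(truth$obesity, runif(n, 30, 45),
                           runif(n, 19, 29.5)))
  hba1c <- one("hba1c", ifelse(truth$t2d, runif(n, 6.5, 9.5),
                        ifelse(truth$prediabetes, runif(n, 5.7, 6.49),
                               runif(n, 4.6, 5.6))))
  glucose <- one("glucose", ifelse(truth$t2d, runif(n, 90, 260),
                                   runif(n, 70, 190)))
  tgQual <- truth$dl_mechanism == "tg"
  tg <- one("tg", ifelse(tgQual, runif(n, 150, 400), runif(n, 60, 149)),
            hour = ifelse(tgQual, runif(n, 6, 8.9), runif(n, 6, 11)))
  hdlCut <- ifelse(truth$sex == "male", 40, 50)
  hdlLow <- truth$dl_mechanism == "hdl_codes"
  hdl <- one("hdl", ifelse(hdlLow, runif(n, 25, hdlCut - 1),
                           runif(n, hdlCut + 2, 85)))

  out <- data.table::rbindlist(list(
    as.data.frame(alt)[, c("id", "analyte", "value", "day", "hour")],
    ast, platelets, albumin, bmi, hba1c, glucose, tg, hdl))
  data.table::setorder(out, id, analyte, day)
  as.data.frame(out)
}

#' Emit diagnosis codes and medication records
#'
#' Planted excluded participants receive an exclusionary liver-disease /
#' alcohol-use code (category drawn with weights matching the study's
#' exclusion composition); hypertension, dyslipidemia, T2D and prediabetes
#' truths generate their code and prescription evidence (two dyslipidemia
#' codes with a low HDL, at least two diabetes-medication days, etc.);
#' statins are prescribed independently of dyslipidemia so a statin alone
#' never implies the flag. Codes are emitted with dots (e.g. `401.9`) to
#' exercise normalization.
#'
#' @inheritParams emitLabSeries
#' @return list with data.frames `codes` (`id`, `system`, `code`, `day`)
#'   and `meds` (`id`, `drug_class`, `day`).
#' @export
emitCodesAndMeds <- function(truth, config, seed = 1L) {
  set.seed(seed)
  n <- nrow(truth)
  codeRows <- list()
  medRows <- list()
  add <- function(ids, system, code, day) {
    if (!length(ids)) return(NULL)
    data.frame(id = ids, system = system, code = code, day = day,
               stringsAsFactors = FALSE)
  }

  # exclusionary codes: composition ~ alcohol 72.6%, viral 11.3%, other 16.1%
  exc <- which(truth$excluded)
  if (length(exc)) {
    cat_codes <- list(
      alcohol_related = c("571.2", "K70.30", "303.90", "F10.20"),
      viral_hepatitis = c("070.54", "B18.2", "B18.1"),
      metabolic_hereditary = c("275.0", "E83.110"),
      cholestatic = c("571.6", "K74.3"),
      liver_metastasis = c("197.7", "C78.7")
    )
    cats <- sample(names(cat_codes), length(exc), replace = TRUE,
                   prob = c(0.726, 0.113, 0.054, 0.054, 0.053))
    code <- vapply(cats, function(cc) sample(cat_codes[[cc]], 1L), "")
    sys <- ifelse(grepl("^[0-9]", code), "ICD9", "ICD10")
    codeRows$exclusion <- add(truth$id[exc], sys, code,
                              -sample.int(1500L, length(exc), replace = TRUE))
    truthCat <- cats
  } else truthCat <- character()

  htn <- which(truth$hypertension)
  if (length(htn)) {
    code <- sample(c("401.9", "401.1", "I10", "I11.9"), length(htn),
                   replace = TRUE)
    codeRows$htn <- add(truth$id[htn],
                        ifelse(grepl("^[0-9]", code), "ICD9", "ICD10"),
                        code, -sample.int(1200L, length(htn), replace = TRUE))
  }

  dlc <- which(truth$dl_mechanism == "hdl_codes")
  if (length(dlc)) {
    d1 <- -sample.int(1200L, length(dlc), replace = TRUE)
    codeRows$dl <- rbind(
      add(truth$id[dlc], "ICD9", "272.4", d1),
      add(truth$id[dlc], "ICD10", "E78.5", d1 - 30L))
  }

  t2d <- which(truth$t2d)
  if (length(t2d)) {
    withCode <- t2d[runif(length(t2d)) < 0.6]
    if (length(withCode)) {
      code <- sample(c("250.00", "E11.9", "E11.65"), length(withCode),
                     replace = TRUE)
      codeRows$t2d <- add(truth$id[withCode],
                          ifelse(grepl("^[0-9]", code), "ICD9", "ICD10"),
                          code,
                          -sample.int(1200L, length(withCode), replace = TRUE))
    }
    withMed <- t2d[runif(length(t2d)) < 0.7]
    if (length(withMed)) {
      d1 <- -sample.int(600L, length(withMed), replace = TRUE)
      medRows$dm <- rbind(
        data.frame(id = truth$id[withMed], drug_class = "diabetes_oral",
                   day = d1),
        data.frame(id = truth$id[withMed], drug_class = "diabetes_oral",
                   day = d1 - 90L))
      ins <- withMed[runif(length(withMed)) < 0.2]
      if (length(ins))
        medRows$ins <- data.frame(id = truth$id[ins], drug_class = "insulin",
                                  day = -sample.int(600L, length(ins),
                                                    replace = TRUE))
    }
  }

  pre <- which(truth$prediabetes)
  preCode <- pre[runif(length(pre)) < 0.5]
  if (length(preCode)) {
    code <- sample(c("790.21", "R73.09", "R73.01"), length(preCode),
                   replace = TRUE)
    codeRows$pre <- add(truth$id[preCode],
                        ifelse(grepl("^[0-9]", code), "ICD9", "ICD10"),
                        code,
                        -sample.int(1200L, length(preCode), replace = TRUE))
  }

  fib <- which(truth$dl_mechanism == "fibrate")
  if (length(fib))
    medRows$fib <- data.frame(id = truth$id[fib], drug_class = "fibrate",
                              day = -sample.int(900L, length(fib),
                                                replace = TRUE))
  statin <- which(runif(n) < 0.3)
  if (length(statin))
    medRows$statin <- data.frame(id = truth$id[statin],
                                 drug_class = "statin",
                                 day = -sample.int(900L, length(statin),
                                                   replace = TRUE))

  codesDf <- if (length(codeRows)) as.data.frame(
    data.table::rbindlist(codeRows)) else
    data.frame(id = character(), system = character(), code = character(),
               day = integer())
  medsDf <- if (length(medRows)) as.data.frame(
    data.table::rbindlist(medRows)) else
    data.frame(id = character(), drug_class = character(), day = integer())
  list(codes = codesDf, meds = medsDf,
       exclusion_category = stats::setNames(truthCat, truth$id[exc]))
}

#' Simulate two-rater chart adjudication
#'
#' Each rater independently calls NAFLD yes/no given the true label, with
#' the stated sensitivity and specificity. Stand-in for manual chart review
#' when assessing the validation-metric machinery.
#'
#' @param truth logical vector (or `"case"`/`"control"` character) of true
#'   disease status.
#' @param sensitivity,specificity per-rater probabilities in [0,1].
#' @param nRaters number of raters (default 2).
#' @param seed integer seed.
#' @return list with `calls` (n x nRaters logical matrix), `raterTable`
#'   (2x2 cross-tabulation of raters 1 and 2) and `truthTables` (one 2x2
#'   rater-vs-truth table per rater). Tables are ordered yes, no.
#' @examples
#' adj <- simulateAdjudication(rep(c(TRUE, FALSE), 50), 0.95, 0.95, seed = 1)
#' adj$raterTable
#' @export
simulateAdjudication <- function(truth, sensitivity, specificity,
                                 nRaters = 2L, seed = 1L) {
  if (is.character(truth)) truth <- truth == "case"
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 ||
      specificity > 1)
    stop("sensitivity and specificity must lie in [0, 1]")
  set.seed(seed)
  n <- length(truth)
  p <- ifelse(truth, sensitivity, 1 - specificity)
  calls <- matrix(stats::rbinom(n * nRaters, 1L, rep(p, nRaters)) == 1L,
                  nrow = n, ncol = nRaters,
                  dimnames = list(NULL, paste0("rater", seq_len(nRaters))))
  lev <- c("yes", "no")
  f <- function(x) factor(ifelse(x, "yes", "no"), levels = lev)
  raterTable <- table(rater1 = f(calls[, 1L]), rater2 = f(calls[, 2L]))
  truthTables <- lapply(seq_len(nRaters), function(j)
    table(rater = f(calls[, j]), truth = f(truth)))
  names(truthTables) <- colnames(calls)
  list(calls = calls, raterTable = unclass(raterTable),
       truthTables = lapply(truthTables, unclass))
}

#' Simulate a complete synthetic EHR cohort
#'
#' Runs the full generator: Hardy-Weinberg genotypes per ancestry, logistic
#' planting of case status from the panel's additive effects (intercept
#' calibrated to the target prevalence), exclusion and intermediate-ALT
#' overlays, metabolic risk-factor truth conditional on status, and the
#' longitudinal lab / code / medication tables that encode that truth.
#' Every stage derives its own sub-seed from `config$seed`, so the whole
#' cohort is reproducible and individual stages can be re-run in isolation.
#'
#' @param config a [simConfig()].
#' @param variants variant annotation data.frame with a `beta` column of
#'   planted log-odds effects (default [nafldVariantPanel()]).
#' @return a [SyntheticCohort-class] object.
#' @examples
#' sc <- simulateCohort(simConfig(n = 300, seed = 11))
#' sc
#' @export
simulateCohort <- function(config = simConfig(),
                           variants = nafldVariantPanel()) {
  stopifnot(inherits(config, "simConfig"))
  nAnc <- round(config$n * config$ancestryMix)
  nAnc[1L] <- config$n - sum(nAnc[-1L])
  ses <- mapply(function(anc, n, k) {
    sampleGenotypes(variants, n = n, ancestry = anc,
                    seed = .stageSeed(config$seed, "genotypes") + k)
  }, names(nAnc), nAnc, seq_along(nAnc), SIMPLIFY = FALSE)
  geno <- do.call(SummarizedExperiment::cbind, ses)
  ids <- colnames(geno)
  n <- length(ids)

  set.seed(.stageSeed(config$seed, "covariates"))
  sex <- ifelse(runif(n) < config$fractionFemale, "female", "male")
  age <- pmin(pmax(rnorm(n, config$ageMean, config$ageSD), 20), 100)
  pcs <- matrix(rnorm(n * 10L), nrow = n,
                dimnames = list(NULL, paste0("PC", 1:10)))
  audit <- stats::rbinom(n, 12L, config$auditCProb)
  parts <- data.frame(id = ids, sex = sex, age_at_enrollment = age,
                      ancestry = as.character(
                        SummarizedExperiment::colData(geno)$ancestry),
                      pcs, audit_c = audit, stringsAsFactors = FALSE)

  st <- assignCaseStatus(geno, targetPrevalence = config$targetPrevalence,
                         seed = .stageSeed(config$seed, "status"))
  set.seed(.stageSeed(config$seed, "status") + 7L)
  excluded <- runif(n) < config$exclusionFraction
  indeterminate <- !excluded & runif(n) < config$indeterminateFraction

  met <- .planMetabolicTruth(st$status, config$metabolicRates,
                             .stageSeed(config$seed, "metabolic"))
  truth <- data.frame(id = ids, sex = sex, age_at_enrollment = age,
                      status = st$status, prob = st$prob,
                      excluded = excluded, indeterminate = indeterminate,
                      met, stringsAsFactors = FALSE)
  truth$expected_stratum <- ifelse(excluded, "excluded",
                            ifelse(indeterminate, "indeterminate",
                                   truth$status))

  labsDf <- emitLabSeries(truth, config,
                          seed = .stageSeed(config$seed, "labs"))
  cm <- emitCodesAndMeds(truth, config,
                         seed = .stageSeed(config$seed, "codes"))
  truth$exclusion_category <- NA_character_
  if (length(cm$exclusion_category))
    truth$exclusion_category[match(names(cm$exclusion_category), truth$id)] <-
      cm$exclusion_category

  cd <- SummarizedExperiment::colData(geno)
  cd$sex <- sex
  cd$age_at_enrollment <- age
  SummarizedExperiment::colData(geno) <- cd

  new("SyntheticCohort", participants = parts, labs = labsDf,
      codes = cm$codes, meds = cm$meds, genotypes = geno, truth = truth,
      config = unclass(config))
}
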