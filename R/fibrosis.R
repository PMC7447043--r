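#' FIB-4 fibrosis index
#'
#' `FIB4 = age [years] * AST [U/L] / (platelets [10^9/L] * sqrt(ALT [U/L]))`.
#' Platelet counts reported in cells/uL should be divided by 1e9/L at the
#' reader (150,000/uL = 150).
#'
#' @param age years.
#' @param ast,alt aminotransferases, U/L; `alt` must be positive.
#' @param platelets platelet count, 10^9/L; must be positive.
#' @return numeric score(s).
#' @examples
#' fib4(age = 61, ast = 60, alt = 40, platelets = 150)
#' @export
fib4 <- function(age, ast, alt, platelets) {
  if (any(alt <= 0, na.rm = TRUE) || any(platelets <= 0, na.rm = TRUE))
    stop("alt and platelets must be positive")
  age * ast / (platelets * sqrt(alt))
}

#' NAFLD fibrosis score
#'
#' `NFS = -1.675 + 0.037*age + 0.094*BMI + 1.13*dysglycemia +
#' 0.99*(AST/ALT) - 0.013*platelets - 0.66*albumin`, where the dysglycemia
#' indicator is diabetes OR prediabetes (the phenotype's own variant of the
#' score's original impaired-fasting-glucose/diabetes term).
#'
#' @param age years.
#' @param bmi kg/m^2.
#' @param diabetes logical or 0/1: diabetes or prediabetes.
#' @param ast,alt U/L; `alt` must be positive.
#' @param platelets 10^9/L.
#' @param albumin g/dL.
#' @return numeric score(s).
#' @examples
#' nfs(age = 60, bmi = 31, diabetes = 1, ast = 40, alt = 50,
#'     platelets = 220, albumin = 4)
#' @export
nfs <- function(age, bmi, diabetes, ast, alt, platelets, albumin) {
  if (any(alt <= 0, na.rm = TRUE))
    stop("alt must be positive")
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.numeric(diabetes) +
    0.99 * (ast / alt) - 0.013 * platelets - 0.66 * albumin
}

#' Advanced-fibrosis and low-platelet flags
#'
#' FIB-4 flags strictly above 2.670; the NFS flag defaults to `>= 0.676`
#' (the convention under which case counts are reported) with
#' `nfsStrict = TRUE` switching to a strict `> 0.676`; low platelets is
#' `< 150` (10^9/L), a portal-hypertension surrogate.
#'
#' @param fib4Score,nfsScore scores from [fib4()] / [nfs()].
#' @param platelets 10^9/L.
#' @param nfsStrict use strict `>` for the NFS boundary.
#' @param fib4Cutoff,nfsCutoff,plateletCutoff the published cutoffs.
#' @return data.frame with logical `fib4_advanced`, `nfs_advanced`,
#'   `low_platelets`.
#' @examples
#' advancedFibrosis(2.671, 0.676, 149)
#' @export
advancedFibrosis <- function(fib4Score, nfsScore, platelets,
                             nfsStrict = FALSE,
                             fib4Cutoff = 2.670, nfsCutoff = 0.676,
                             plateletCutoff = 150) {
  data.frame(
    fib4_advanced = fib4Score > fib4Cutoff,
    nfs_advanced = if (nfsStrict) nfsScore > nfsCutoff else
      nfsScore >= nfsCutoff,
    low_platelets = platelets < plateletCutoff
  )
}

#' Fibrosis scores at enrollment for a cohort
#'
#' Builds each participant's score inputs from the most recent
#' pre-enrollment observation per analyte and the derived
#' diabetes-or-prediabetes flag, then evaluates FIB-4, NFS and the advanced
#' flags. Participants missing a required analyte get `NA` scores.
#'
#' @inheritParams classifyCohort
#' @param metabolic optional precomputed [metabolicFlags()] output.
#' @param nfsStrict see [advancedFibrosis()].
#' @return data.frame: `id`, the inputs, `fib4`, `nfs` and the three flags.
#' @export
fibrosisScores <- function(participantsDf, labsDf, codesDf, medsDf,
                           metabolic = NULL, nfsStrict = FALSE,
                           codePatterns = defaultCodePatterns()) {
  ids <- participantsDf$id
  labsDt <- data.table::as.data.table(labsDf)
  if (!"hour" %in% names(labsDt)) labsDt[, hour := NA_real_]
  val <- function(what) {
    r <- .mostRecent(labsDt, what)
    r$value[match(ids, r$id)]
  }
  if (is.null(metabolic))
    metabolic <- metabolicFlags(labsDf, codesDf, medsDf, participantsDf,
                                codePatterns)
  metabolic <- metabolic[match(ids, metabolic$id), ]
  inp <- data.frame(
    id = ids,
    age = participantsDf$age_at_enrollment,
    ast = val("ast"), alt = val("alt"),
    platelets = val("platelets"), bmi = val("bmi"),
    albumin = val("albumin"),
    diabetes_or_prediabetes = metabolic$t2d | metabolic$prediabetes,
    stringsAsFactors = FALSE
  )
  ok4 <- stats::complete.cases(inp[, c("age", "ast", "alt", "platelets")]) &
    inp$alt > 0 & inp$platelets > 0
  okN <- stats::complete.cases(
    inp[, c("age", "bmi", "ast", "alt", "platelets", "albumin")]) &
    inp$alt > 0
  inp$fib4 <- NA_real_
  inp$fib4[ok4] <- fib4(inp$age[ok4], inp$ast[ok4], inp$alt[ok4],
                        inp$platelets[ok4])
  inp$nfs <- NA_real_
  inp$nfs[okN] <- nfs(inp$age[okN], inp$bmi[okN],
                      inp$diabetes_or_prediabetes[okN], inp$ast[okN],
                      inp$alt[okN], inp$platelets[okN], inp$albumin[okN])
  cbind(inp, advancedFibrosis(inp$fib4, inp$nfs, inp$platelets,
                              nfsStrict = nfsStrict))
}
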