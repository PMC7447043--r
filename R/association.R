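#' Fit one additive-genotype regression
#'
#' Logistic regression (Wald tests) for binary outcomes, least squares for
#' continuous outcomes, with allele dosage entering additively. The
#' covariate sets are the three nested adjustment models: Model 1 age, sex
#' and the first 10 genetic principal components; Model 2 adds the AUDIT-C
#' alcohol consumption score; Model 3 adds the metabolic risk factors
#' (diabetes-or-prediabetes, hypertension, dyslipidemia, obesity).
#' Degenerate designs (constant dosage, non-convergence, separation) are
#' flagged non-estimable rather than erroring.
#'
#' @param dosage numeric dosages in [0,2] (continuous accepted).
#' @param outcome binary (logical / "case"-"control" / 0-1) or continuous
#'   numeric.
#' @param covariates data.frame or matrix of covariates (may be NULL).
#' @param rsid,stratum labels carried into the result.
#' @return one-row data.frame: `rsid`, `stratum`, `beta`, `se`, `p`, `or_`,
#'   `ci_lo`, `ci_hi` (exp scale, binary outcomes only), `n`, `n_cases`,
#'   `n_controls`, `estimable`.
#' @examples
#' set.seed(1)
#' d <- rbinom(500, 2, 0.3)
#' y <- rbinom(500, 1, plogis(-1 + 0.3 * d))
#' fitSnpModel(d, y)
#' @export
fitSnpModel <- function(dosage, outcome, covariates = NULL,
                        rsid = NA_character_, stratum = NA_character_) {
  if (is.character(outcome)) outcome <- outcome == "case"
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  binary <- all(outcome %in% c(0L, 1L))
  df <- data.frame(.y = outcome, .dosage = as.numeric(dosage))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  nca <- if (binary) sum(df$.y == 1L) else NA_integer_
  nco <- if (binary) sum(df$.y == 0L) else NA_integer_

  bad <- function() data.frame(
    rsid = rsid, stratum = stratum, beta = NA_real_, se = NA_real_,
    p = NA_real_, or_ = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    n = n, n_cases = nca, n_controls = nco, estimable = FALSE,
    stringsAsFactors = FALSE)

  if (n == 0L || length(unique(df$.dosage)) < 2L) return(bad())
  if (binary && (nca == 0L || nco == 0L)) return(bad())

  fml <- stats::as.formula(paste(".y ~ .dosage",
    if (ncol(df) > 2L)
      paste("+", paste(setdiff(names(df), c(".y", ".dosage")),
                       collapse = " + ")) else ""))
  fit <- tryCatch({
    if (binary) stats::glm(fml, family = stats::binomial(), data = df)
    else stats::lm(fml, data = df)
  }, error = function(e) NULL, warning = function(w) {
    # glm.fit warnings signal separation / non-convergence
    suppressWarnings(
      if (binary) stats::glm(fml, family = stats::binomial(), data = df)
      else stats::lm(fml, data = df))
  })
  if (is.null(fit)) return(bad())
  cf <- stats::coef(fit)
  if (is.na(cf[".dosage"])) return(bad())
  beta <- unname(cf[".dosage"])
  se <- sqrt(diag(stats::vcov(fit)))[".dosage"]
  se <- unname(se)
  if (!is.finite(beta) || !is.finite(se) || se <= 0 || se > 100 ||
      abs(beta) > 50 || (binary && !isTRUE(fit$converged)))
    return(bad())
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(
    rsid = rsid, stratum = stratum, beta = beta, se = se, p = p,
    or_ = if (binary) exp(beta) else NA_real_,
    ci_lo = if (binary) exp(beta - 1.959963984540054 * se) else NA_real_,
    ci_hi = if (binary) exp(beta + 1.959963984540054 * se) else NA_real_,
    n = n, n_cases = nca, n_controls = nco, estimable = TRUE,
    stringsAsFactors = FALSE)
}

#' Build the nested adjustment covariate sets
#'
#' @param participantsDf participant table with `age_at_enrollment`, `sex`,
#'   `PC1`..`PC10`, `audit_c`.
#' @param metabolic [metabolicFlags()] output aligned to participants
#'   (required for model 3).
#' @param model 1, 2 or 3.
#' @return data.frame of numeric covariates.
#' @export
modelCovariates <- function(participantsDf, metabolic = NULL, model = 1L) {
  stopifnot(model %in% 1:3)
  pcs <- participantsDf[, paste0("PC", 1:10)]
  out <- data.frame(age = participantsDf$age_at_enrollment,
                    sex_male = as.integer(participantsDf$sex == "male"),
                    pcs)
  if (model >= 2L) out$audit_c <- participantsDf$audit_c
  if (model >= 3L) {
    if (is.null(metabolic)) stop("model 3 requires metabolic flags")
    metabolic <- metabolic[match(participantsDf$id, metabolic$id), ]
    out$dm_or_prediab <- as.integer(metabolic$t2d | metabolic$prediabetes)
    out$hypertension <- as.integer(metabolic$hypertension)
    out$dyslipidemia <- as.integer(metabolic$dyslipidemia)
    out$obesity <- as.integer(metabolic$obesity)
  }
  out
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines per-stratum estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\hat\beta = \sum w_i b_i / \sum w_i}, \eqn{se = (\sum w_i)^{-1/2}},
#' two-sided p from the standard normal.
#'
#' @param beta per-stratum effect estimates (or a data.frame from
#'   [fitSnpModel()] rows with `beta`/`se` columns, non-estimable rows
#'   dropped).
#' @param se per-stratum standard errors (all > 0).
#' @return list: `beta`, `se`, `z`, `p`, `k`, `weights`.
#' @examples
#' metaFixedEffects(c(0.1, 0.3), c(0.1, 0.2))
#' @export
metaFixedEffects <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    keep <- if ("estimable" %in% names(beta)) beta$estimable else
      rep(TRUE, nrow(beta))
    se <- beta$se[keep]; beta <- beta$beta[keep]
  }
  if (!length(beta)) stop("no estimable strata to combine")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)),
       k = length(beta), weights = w)
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum w_i (b_i - \hat\beta)^2} with \eqn{w_i = 1/se_i^2} and the
#' fixed-effects combined estimate \eqn{\hat\beta}; the p-value is the
#' upper tail of a chi-square with k-1 degrees of freedom. Undefined
#' (all-NA) for fewer than two strata.
#'
#' @inheritParams metaFixedEffects
#' @param combinedBeta optionally precomputed combined estimate.
#' @return list: `q`, `df`, `p`.
#' @examples
#' cochranQ(c(0.1, 0.3), c(0.1, 0.2))
#' @export
cochranQ <- function(beta, se = NULL, combinedBeta = NULL) {
  if (is.data.frame(beta)) {
    keep <- if ("estimable" %in% names(beta)) beta$estimable else
      rep(TRUE, nrow(beta))
    se <- beta$se[keep]; beta <- beta$beta[keep]
  }
  k <- length(beta)
  if (k < 2L) return(list(q = NA_real_, df = NA_integer_, p = NA_real_))
  if (any(se <= 0)) stop("all standard errors must be positive")
  if (is.null(combinedBeta))
    combinedBeta <- metaFixedEffects(beta, se)$beta
  w <- 1 / se^2
  q <- sum(w * (beta - combinedBeta)^2)
  list(q = q, df = k - 1L, p = stats::pchisq(q, df = k - 1L,
                                             lower.tail = FALSE))
}

#' Significance tier of a p-value
#'
#' Genome-wide 5e-8; experiment-wide 1e-5 (correction for ~5,000 regional
#' tests); replication 6.25e-3 (Bonferroni over 8 independent loci);
#' otherwise none. The strongest satisfied tier is reported.
#'
#' @param p p-value(s) in (0, 1].
#' @param genomeWide,experimentWide,replication the tier thresholds.
#' @return character vector in
#'   `c("genome_wide","experiment_wide","replication","none")`.
#' @examples
#' classifySignificance(c(1e-9, 0.005, 0.01))
#' @export
classifySignificance <- function(p, genomeWide = 5e-8,
                                 experimentWide = 1e-5,
                                 replication = 6.25e-3) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p must lie in (0, 1]")
  ifelse(p < genomeWide, "genome_wide",
  ifelse(p < experimentWide, "experiment_wide",
  ifelse(p < replication, "replication", "none")))
}

#' Ancestry-stratified association with trans-ethnic meta-analysis
#'
#' For each variant in the genotype container, fits the additive model
#' within each ancestry stratum, combines strata by fixed-effects
#' inverse-variance meta-analysis, and attaches Cochran's Q heterogeneity
#' and the significance tier.
#'
#' @param genotypesSe `SummarizedExperiment` of dosages (variants x
#'   participants) with `rowData` annotations.
#' @param outcome vector aligned to participants (binary or continuous);
#'   participants with `NA` outcome (e.g. excluded / indeterminate) are
#'   dropped.
#' @param participantsDf participant table aligned to `colnames(genotypesSe)`.
#' @param metabolic [metabolicFlags()] output (model 3).
#' @param model adjustment model 1, 2 or 3.
#' @param byAncestry stratify by the `ancestry` column (TRUE) or fit a
#'   single pooled stratum.
#' @return list with `strata` (per-stratum fit rows) and `meta`
#'   (per-variant combined rows: `beta`, `se`, `or_`, `ci_lo`, `ci_hi`,
#'   `p`, `q`, `q_df`, `het_p`, `k`, `tier`).
#' @export
associateVariants <- function(genotypesSe, outcome, participantsDf,
                              metabolic = NULL, model = 1L,
                              byAncestry = TRUE) {
  dos <- SummarizedExperiment::assay(genotypesSe, "dosage")
  stopifnot(ncol(dos) == nrow(participantsDf))
  keep <- !is.na(outcome)
  anc <- if (byAncestry) participantsDf$ancestry else
    rep("ALL", nrow(participantsDf))
  rsids <- rownames(dos)
  binaryOut <- is.character(outcome) || is.logical(outcome) ||
    all(stats::na.omit(outcome) %in% c(0, 1))

  strataRows <- list()
  metaRows <- list()
  for (v in rsids) {
    fits <- lapply(unique(anc[keep]), function(a) {
      sel <- keep & anc == a
      fitSnpModel(dos[v, sel], outcome[sel],
                  modelCovariates(participantsDf[sel, , drop = FALSE],
                                  if (is.null(metabolic)) NULL else
                                    metabolic[sel, , drop = FALSE],
                                  model = model),
                  rsid = v, stratum = a)
    })
    fits <- do.call(rbind, fits)
    strataRows[[v]] <- fits
    est <- fits[fits$estimable, , drop = FALSE]
    if (nrow(est)) {
      m <- metaFixedEffects(est$beta, est$se)
      q <- cochranQ(est$beta, est$se, combinedBeta = m$beta)
      metaRows[[v]] <- data.frame(
        rsid = v, beta = m$beta, se = m$se, z = m$z, p = m$p,
        or_ = if (binaryOut) exp(m$beta) else NA_real_,
        ci_lo = if (binaryOut) exp(m$beta - 1.959963984540054 * m$se)
          else NA_real_,
        ci_hi = if (binaryOut) exp(m$beta + 1.959963984540054 * m$se)
          else NA_real_,
        q = q$q, q_df = q$df, het_p = q$p, k = m$k,
        tier = classifySignificance(m$p),
        n = sum(est$n), stringsAsFactors = FALSE)
    }
  }
  strata <- do.call(rbind, strataRows)
  rownames(strata) <- NULL
  meta <- do.call(rbind, metaRows)
  ann <- as.data.frame(SummarizedExperiment::rowData(genotypesSe))
  if (!is.null(meta)) {
    rownames(meta) <- NULL
    keepCols <- intersect(c("gene", "rsid", "chrom", "pos",
                            "effect_allele", "eaf"), names(ann))
    meta <- merge(ann[, keepCols, drop = FALSE], meta, by = "rsid",
                  sort = FALSE)
  }
  list(strata = strata, meta = meta)
}
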