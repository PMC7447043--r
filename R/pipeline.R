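#' Write / read the five cohort tables
#'
#' The EHR-shaped tables (participants, labs, codes, meds) are written as
#' CSV, the dosage matrix as a CSV with variants as rows, the variant
#' annotations as a CSV, and a manifest JSON recording the configuration
#' and seed.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeCohortTables <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  data.table::fwrite(participants(cohort), p("participants.csv"))
  data.table::fwrite(labs(cohort), p("labs.csv"))
  data.table::fwrite(codes(cohort), p("codes.csv"))
  data.table::fwrite(meds(cohort), p("meds.csv"))
  geno <- genotypes(cohort)
  dos <- SummarizedExperiment::assay(geno, "dosage")
  data.table::fwrite(data.frame(rsid = rownames(dos), dos,
                                check.names = FALSE), p("dosages.csv"))
  data.table::fwrite(
    as.data.frame(SummarizedExperiment::rowData(geno)), p("variants.csv"))
  jsonlite::write_json(cohort@config, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(p(c("participants.csv", "labs.csv", "codes.csv", "meds.csv",
                "dosages.csv", "variants.csv", "manifest.json")))
}

#' @rdname writeCohortTables
#' @return `readCohortTables`: list of data.frames plus the dosage
#'   `SummarizedExperiment`.
#' @export
readCohortTables <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("participants.csv", "labs.csv", "codes.csv", "meds.csv"))
    if (!file.exists(p(f))) stop("missing input table: ", f)
  out <- list(
    participants = as.data.frame(data.table::fread(p("participants.csv"))),
    labs = as.data.frame(data.table::fread(p("labs.csv"))),
    codes = as.data.frame(data.table::fread(p("codes.csv"),
                                            colClasses = list(
                                              character = "code"))),
    meds = as.data.frame(data.table::fread(p("meds.csv")))
  )
  if (file.exists(p("dosages.csv")) && file.exists(p("variants.csv"))) {
    dosDf <- as.data.frame(data.table::fread(p("dosages.csv")))
    variants <- as.data.frame(data.table::fread(p("variants.csv")))
    dos <- as.matrix(dosDf[, -1, drop = FALSE])
    rownames(dos) <- dosDf$rsid
    out$genotypes <- SummarizedExperiment::SummarizedExperiment(
      assays = list(dosage = dos),
      rowData = S4Vectors::DataFrame(variants, row.names = variants$rsid))
  }
  out
}

#' Pipeline run configuration
#'
#' One config drives the whole simulate-phenotype-score-associate-validate
#' run. Every threshold of the method is a named key with the published
#' value as default: ALT cutoffs via the definition, 183/730-day pair
#' bounds, fibrosis cutoffs 2.670 / 0.676 / 150, and the significance
#' tiers 5e-8 / 1e-5 / 6.25e-3.
#'
#' @param n cohort size.
#' @param seed master seed.
#' @param definition phenotype definition name (see [nafldDefinitions()]).
#' @param models adjustment models to fit.
#' @param raterSensitivity,raterSpecificity adjudication simulator settings.
#' @param nfsStrict strict NFS boundary (see [advancedFibrosis()]).
#' @param sim additional [simConfig()] overrides (named list).
#' @return list of class `"nafldRunConfig"`.
#' @export
nafldRunConfig <- function(n = 5000, seed = 1L,
                           definition = "alt_threshold",
                           models = c(1L, 2L, 3L),
                           raterSensitivity = 0.95,
                           raterSpecificity = 0.95,
                           nfsStrict = FALSE,
                           sim = list()) {
  cfg <- list(n = n, seed = as.integer(seed), definition = definition,
              models = models, raterSensitivity = raterSensitivity,
              raterSpecificity = raterSpecificity, nfsStrict = nfsStrict,
              sim = sim)
  class(cfg) <- c("nafldRunConfig", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [nafldRunConfig()] arguments.
#'   Note the `n` key must be written quoted (`"n": 5000`): YAML 1.1 parsers
#'   otherwise read a bare `n` as a boolean.
#' @return a `nafldRunConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(nafldRunConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(nafldRunConfig, y)
}

#' Run the full pipeline
#'
#' Simulate a cohort, classify it under the configured phenotype
#' definition, score fibrosis at enrollment, fit the ancestry-stratified
#' association models with trans-ethnic meta-analysis, simulate chart
#' adjudication and compute the validation metrics, and produce the cohort
#' accounting table. When `outDir` is given, all six artifacts (calls,
#' scores, per-stratum association, meta-analysis, validation, accounting)
#' are written as CSV/JSON alongside a manifest recording config, seed and
#' package version.
#'
#' @param config an [nafldRunConfig()] (or path to a YAML file).
#' @param outDir optional output directory.
#' @return list with `cohort`, `calls`, `scores`, `association` (per
#'   model: strata + meta), `validation`, `accounting`, `manifest`.
#' @examples
#' \donttest{
#' res <- runPipeline(nafldRunConfig(n = 400, seed = 42))
#' res$accounting
#' }
#' @export
runPipeline <- function(config = nafldRunConfig(), outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "nafldRunConfig"))
  defs <- nafldDefinitions()
  if (!config$definition %in% names(defs))
    stop("unknown phenotype definition: ", config$definition)
  definition <- defs[[config$definition]]

  simArgs <- c(list(n = config$n, seed = config$seed), config$sim)
  cohort <- simulateCohort(do.call(simConfig, simArgs))
  parts <- participants(cohort)

  calls <- classifyCohort(parts, labs(cohort), codes(cohort), meds(cohort),
                          definition = definition)
  met <- calls[, c("id", "obesity", "dyslipidemia", "hypertension", "t2d",
                   "prediabetes", "any_metabolic")]
  scores <- fibrosisScores(parts, labs(cohort), codes(cohort), meds(cohort),
                           metabolic = met, nfsStrict = config$nfsStrict)

  outcome <- ifelse(calls$stratum == "case", 1L,
             ifelse(calls$stratum == "control", 0L, NA_integer_))
  association <- lapply(config$models, function(m)
    associateVariants(genotypes(cohort), outcome, parts, metabolic = met,
                      model = m))
  names(association) <- paste0("model", config$models)

  truth <- cohortTruth(cohort)
  phenoPos <- calls$stratum == "case"
  adj <- simulateAdjudication(truth$status == "case",
                              config$raterSensitivity,
                              config$raterSpecificity,
                              seed = .stageSeed(config$seed,
                                                "adjudication"))
  # review sample = phenotype-positive participants; gold standard = the
  # raters' consensus adjudication
  consensus <- adj$calls[, 1L] & adj$calls[, 2L]
  validation <- validateCalls(phenoPos[phenoPos], consensus[phenoPos],
                              rater1 = adj$calls[phenoPos, 1L],
                              rater2 = adj$calls[phenoPos, 2L])
  accounting <- cohortAccounting(calls)

  manifest <- list(package = "nafldphen",
                   version = as.character(utils::packageVersion("nafldphen")),
                   config = unclass(config),
                   timestamp = NA)
  res <- list(cohort = cohort, calls = calls, scores = scores,
              association = association, validation = validation,
              accounting = accounting, manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outDir, f)
    data.table::fwrite(calls, p("calls.csv"))
    data.table::fwrite(scores, p("scores.csv"))
    for (m in names(association)) {
      data.table::fwrite(association[[m]]$strata,
                         p(sprintf("assoc_strata_%s.csv", m)))
      data.table::fwrite(association[[m]]$meta,
                         p(sprintf("assoc_meta_%s.csv", m)))
    }
    jsonlite::write_json(
      list(ppv = validation$ppv, kappa = validation$kappa,
           table = validation$table),
      p("validation.json"), auto_unbox = TRUE, digits = NA)
    data.table::fwrite(accounting, p("accounting.csv"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  res
}
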