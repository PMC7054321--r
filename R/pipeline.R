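#' Assemble a pipeline run configuration
#'
#' Bundles every tunable of the end-to-end workflow (upload, outcome/family
#' choice, optional FDR screen, penalty choice, fit, prediction-power CV,
#' post-selection inference, reporting) with the documented defaults:
#' `q = 0.05`, `foldsPredict = 5`, `zscoreCutoff = 2`, prevalence 0.01 for
#' mutation indicators and 0.02 for expression abnormalities, threshold 0.5
#' on the probability scale.
#'
#' @param data a ready [MolecularDataSet-class], or NULL when paths are
#'   given.
#' @param matrixPath,clinicalPath delimited input files (see
#'   [readMolecularMatrix()], [readClinicalTable()]).
#' @param kind covariate kind of the matrix file.
#' @param binarize dichotomize Z-scores at `zscoreCutoff` before analysis
#'   (default TRUE for Z-score input: downstream works on abnormality
#'   indicators).
#' @param zscoreCutoff abnormality cutoff.
#' @param prevalenceMin prevalence filter fraction; default 0.01 for binary
#'   mutation input, 0.02 for binarized expression.
#' @param fdr run univariate FDR screening first.
#' @param q FDR threshold.
#' @param penalty penalty family.
#' @param lambda `"cv"` or a positive number.
#' @param foldsTune tuning-CV folds.
#' @param foldsPredict prediction-power CV folds (1 = skip).
#' @param threshold,thresholdScale classification rule.
#' @param standardize,includeClinical passed to [penalizedFit()].
#' @param seed master seed for all randomness.
#' @param outDir output directory (NULL = no files written).
#' @return a validated config list of class `penomicsConfig`.
#' @export
runConfig <- function(data = NULL, matrixPath = NULL, clinicalPath = NULL,
                      kind = c("zscore", "binary"), binarize = NULL,
                      zscoreCutoff = 2, prevalenceMin = NULL,
                      fdr = FALSE, q = 0.05,
                      penalty = c("lasso", "ridge", "adaptive_lasso"),
                      lambda = "cv", foldsTune = 10, foldsPredict = 5,
                      threshold = 0.5,
                      thresholdScale = c("probability", "linear_predictor"),
                      standardize = NULL, includeClinical = FALSE,
                      seed = 1, outDir = NULL) {
  kind <- match.arg(kind)
  penalty <- match.arg(penalty)
  thresholdScale <- match.arg(thresholdScale)
  if (is.null(data) && is.null(matrixPath))
    .err("penomics_domain", "either 'data' or 'matrixPath' is required")
  if (is.null(binarize)) binarize <- identical(kind, "zscore")
  if (is.null(prevalenceMin))
    prevalenceMin <- if (identical(kind, "binary")) 0.01 else 0.02
  cfg <- list(data = data, matrixPath = matrixPath,
              clinicalPath = clinicalPath, kind = kind, binarize = binarize,
              zscoreCutoff = zscoreCutoff, prevalenceMin = prevalenceMin,
              fdr = fdr, q = q, penalty = penalty, lambda = lambda,
              foldsTune = foldsTune, foldsPredict = foldsPredict,
              threshold = threshold, thresholdScale = thresholdScale,
              standardize = standardize,
              includeClinical = includeClinical,
              seed = as.integer(seed), outDir = outDir)
  class(cfg) <- "penomicsConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order -- input, preprocessing
#' (Z-score dichotomization, prevalence filter), optional FDR screening,
#' penalized fit (with CV tuning and the two-stage adaptive refit),
#' post-selection inference (l1 penalties), prediction-power CV, and the
#' model report -- logging every default used. When `outDir` is set, the
#' artifact bundle (screen/fit/inference TSVs, CV JSON, model JSON, run
#' log) is written with the config hash and seed stamped in each name.
#'
#' If screening leaves zero features the pipeline stops early with status
#' `"no_features_passed_screening"` rather than an error; all randomness is
#' traced to `config$seed`.
#'
#' @param config a `penomicsConfig` from [runConfig()].
#' @return a list of stage results: `dataset`, `screen`, `fit`, `inference`,
#'   `cv`, `report`, `status`, `log`, `files`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "penomicsConfig"))
  logLines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    logLines <<- c(logLines, line)
  }
  stamp <- sprintf("%s_seed%d",
                   .configHash(config[setdiff(names(config),
                                              c("data", "outDir"))]),
                   config$seed)
  out <- list(status = "ok", files = character())

  ## stage: input
  ds <- config$data
  if (is.null(ds)) {
    say("reading matrix %s (kind=%s)", config$matrixPath, config$kind)
    M <- readMolecularMatrix(config$matrixPath, kind = config$kind)
    if (config$binarize && identical(config$kind, "zscore")) {
      say("binarizing Z-scores at |z| > %g", config$zscoreCutoff)
      M <- binarizeZscores(M, config$zscoreCutoff)
    }
    say("prevalence filter at >= %g", config$prevalenceMin)
    M <- prevalenceFilter(M, config$prevalenceMin)
    cl <- readClinicalTable(config$clinicalPath)
    ds <- alignDataset(M, cl$outcome,
                       clinical = if (config$includeClinical) cl$clinical)
  } else {
    say("using in-memory dataset (%d features x %d samples)",
        nrow(ds), ncol(ds))
    if (config$binarize && identical(featureKind(ds), "zscore")) {
      say("binarizing Z-scores at |z| > %g then filtering at >= %g",
          config$zscoreCutoff, config$prevalenceMin)
      M <- binarizeZscores(molecularMatrix(covariates(ds), "zscore"),
                           config$zscoreCutoff)
      M <- prevalenceFilter(M, config$prevalenceMin)
      ds <- alignDataset(M, getOutcome(ds))
    }
  }
  out$dataset <- ds
  say("dataset: %d features x %d samples, %s outcome",
      nrow(ds), ncol(ds), outcomeType(ds))

  ## stage: screening
  if (config$fdr) {
    say("FDR screening at q = %g", config$q)
    sr <- screenFeatures(ds, q = config$q,
                         includeClinical = config$includeClinical)
    out$screen <- sr
    if (!any(sr@selected)) {
      say("no features passed screening; stopping")
      out$status <- "no_features_passed_screening"
      out$log <- logLines
      out$files <- .writePipelineFiles(out, config, stamp) %||% character()
      return(out)
    }
    ds <- applyScreen(ds, sr)
    say("%d features pass screening", nrow(ds))
  }

  ## stage: fit
  say("fitting %s (lambda = %s, tuning folds = %d, seed = %d)",
      config$penalty, paste(config$lambda, collapse = ""),
      config$foldsTune, config$seed)
  fit <- if (identical(config$penalty, "adaptive_lasso")) {
    first <- penalizedFit(ds, penalty = "lasso", lambda = config$lambda,
                          standardize = config$standardize,
                          includeClinical = config$includeClinical,
                          nFoldsTune = config$foldsTune, seed = config$seed)
    spec <- adaptiveWeights(first)
    penalizedFit(ds, penalty = "adaptive_lasso", lambda = config$lambda,
                 weights = spec@weights, excluded = spec@excluded,
                 standardize = config$standardize,
                 includeClinical = config$includeClinical,
                 nFoldsTune = config$foldsTune, seed = config$seed)
  } else {
    penalizedFit(ds, penalty = config$penalty, lambda = config$lambda,
                 standardize = config$standardize,
                 includeClinical = config$includeClinical,
                 nFoldsTune = config$foldsTune, seed = config$seed)
  }
  out$fit <- fit
  say("fit done: lambda = %.5g, %d active features",
      fit@lambda, length(activeSet(fit)))

  ## stage: post-selection inference
  if (fit@penalty %in% c("lasso", "adaptive_lasso") &&
      length(activeSet(fit))) {
    say("post-selection inference at lambda = %.5g", fit@lambda)
    out$inference <- tryCatch(selectivePvalues(fit, ds),
                              penomics_error = function(e) {
                                say("inference skipped: %s",
                                    conditionMessage(e))
                                NULL
                              })
  }

  ## stage: prediction-power CV
  if (config$foldsPredict == 1) {
    say("prediction-power cross-validation not performed (1 fold chosen)")
    out$cv <- kfoldCV(ds, nFolds = 1, seed = config$seed)
  } else {
    say("%d-fold prediction-power cross-validation", config$foldsPredict)
    out$cv <- kfoldCV(ds, nFolds = config$foldsPredict, seed = config$seed,
                      screen = config$fdr, q = config$q,
                      penalty = config$penalty, lambda = config$lambda,
                      nFoldsTune = config$foldsTune,
                      standardize = config$standardize,
                      includeClinical = config$includeClinical,
                      threshold = config$threshold,
                      thresholdScale = config$thresholdScale)
  }

  ## stage: report
  out$report <- effectSizes(fit, inference = out$inference,
                            threshold = config$threshold,
                            thresholdScale = config$thresholdScale)
  say("report: %d rows", nrow(out$report@table))
  out$log <- logLines
  out$files <- .writePipelineFiles(out, config, stamp) %||% character()
  out
}

.writePipelineFiles <- function(out, config, stamp) {
  if (is.null(config$outDir)) return(invisible(NULL))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(name) file.path(config$outDir,
                                  sprintf("%s_%s", stamp, name))
  files <- character()
  if (!is.null(out$screen)) {
    sr <- out$screen
    utils::write.table(
      data.frame(feature_id = sr@featureIDs, p_value = sr@pValues,
                 q_value = sr@qValues, selected = sr@selected),
      pth("screen.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, pth("screen.tsv"))
  }
  if (!is.null(out$fit)) {
    co <- out$fit@coefficients
    utils::write.table(
      data.frame(feature_id = names(co), coefficient = unname(co)),
      pth("fit.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(family = out$fit@family, penalty = out$fit@penalty,
           lambda_used = out$fit@lambda, converged = out$fit@converged,
           objective_value = out$fit@objective,
           intercept = out$fit@intercept, seed = config$seed),
      pth("fit.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, pth("fit.tsv"), pth("fit.json"))
  }
  if (!is.null(out$inference)) {
    tab <- out$inference@table
    tab$effect_size <- exp(tab$coefficient)
    utils::write.table(tab, pth("inference.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, pth("inference.tsv"))
  }
  if (!is.null(out$cv) && out$cv@performed) {
    jsonlite::write_json(
      list(family = out$cv@family, n_folds = out$cv@nFolds,
           aggregate = as.list(out$cv@aggregate),
           per_fold = out$cv@perFold, seed = out$cv@seed),
      pth("cv.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, pth("cv.json"))
  }
  if (!is.null(out$report)) {
    jsonlite::write_json(
      list(family = out$report@family, intercept = out$report@intercept,
           threshold = out$report@threshold,
           threshold_scale = out$report@thresholdScale,
           coefficients = as.list(stats::setNames(
             out$report@table$coefficient, out$report@table$featureID))),
      pth("model.json"), auto_unbox = TRUE, digits = NA)
    files <- c(files, pth("model.json"))
  }
  writeLines(out$log, pth("run.log"))
  files <- c(files, pth("run.log"))
  invisible(files)
}
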