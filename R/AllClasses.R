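#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

.KINDS <- c("zscore", "binary")
.FAMILIES <- c("logistic", "cox", "gaussian")
.PENALTIES <- c("ridge", "lasso", "adaptive_lasso")

#' Samples-by-features molecular covariate matrix
#'
#' A thin container around a numeric matrix of molecular covariates with
#' samples in rows and features in columns. `kind = "zscore"` marks
#' continuous expression Z-scores; `kind = "binary"` marks 0/1 alteration
#' indicators (e.g. mutation present / expression abnormal).
#'
#' @slot values numeric matrix, samples x features, with unique dimnames.
#' @slot kind `"zscore"` or `"binary"`.
#' @export
setClass("MolecularMatrix",
  slots = c(values = "matrix", kind = "character"))

setValidity("MolecularMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated sample IDs")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated feature IDs")
  }
  if (length(object@kind) != 1L || !object@kind %in% .KINDS)
    msg <- c(msg, "'kind' must be one of \"zscore\", \"binary\"")
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (length(object@kind) == 1L && identical(object@kind, "binary") &&
      length(v) && !all(v %in% c(0, 1)))
    msg <- c(msg, "binary matrix contains values outside {0, 1}")
  if (length(msg)) msg else TRUE
})

#' Binary clinical outcome
#'
#' @slot sampleIDs character vector of unique sample identifiers.
#' @slot y integer 0/1 outcome per sample.
#' @slot positiveLabel what y = 1 means (e.g. `"invasive"`).
#' @export
setClass("BinaryOutcome",
  slots = c(sampleIDs = "character", y = "integer", positiveLabel = "character"))

setValidity("BinaryOutcome", function(object) {
  msg <- character()
  if (anyDuplicated(object@sampleIDs)) msg <- c(msg, "duplicated sample IDs")
  if (length(object@y) != length(object@sampleIDs))
    msg <- c(msg, "'y' and 'sampleIDs' lengths differ")
  if (anyNA(object@y) || !all(object@y %in% c(0L, 1L)))
    msg <- c(msg, "'y' must be 0/1 with no missing values")
  if (length(unique(object@y)) < 2L)
    msg <- c(msg, "both outcome classes must be present")
  if (length(msg)) msg else TRUE
})

#' Right-censored survival outcome
#'
#' Observed time is min(event time, censoring time); `event` is 1 for an
#' observed event and 0 for right censoring.
#'
#' @slot sampleIDs character vector of unique sample identifiers.
#' @slot time non-negative observed times.
#' @slot event integer 0/1 event indicators.
#' @export
setClass("SurvivalOutcome",
  slots = c(sampleIDs = "character", time = "numeric", event = "integer"))

setValidity("SurvivalOutcome", function(object) {
  msg <- character()
  if (anyDuplicated(object@sampleIDs)) msg <- c(msg, "duplicated sample IDs")
  n <- length(object@sampleIDs)
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "'time', 'event' and 'sampleIDs' lengths differ")
  if (anyNA(object@time) || any(object@time < 0))
    msg <- c(msg, "'time' must be non-negative with no missing values")
  if (anyNA(object@event) || !all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "'event' must be 0/1 with no missing values")
  if (!any(object@event == 1L)) msg <- c(msg, "at least one event is required")
  if (length(msg)) msg else TRUE
})

#' Aligned analysis-ready dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the molecular
#' covariates (assay `"covariates"`, features x samples) together with the
#' outcome and any clinical covariates in `colData`. Built with
#' [alignDataset()]; sample order is identical across all components.
#'
#' @slot featureKind `"zscore"` or `"binary"`.
#' @slot outcomeType `"binary"` or `"survival"`.
#' @slot clinicalCovariates names of unpenalized clinical columns in
#'   `colData` (possibly empty).
#' @export
setClass("MolecularDataSet",
  contains = "SummarizedExperiment",
  slots = c(featureKind = "character", outcomeType = "character",
            clinicalCovariates = "character"))

setValidity("MolecularDataSet", function(object) {
  msg <- character()
  if (!object@featureKind %in% .KINDS) msg <- c(msg, "invalid 'featureKind'")
  if (!object@outcomeType %in% c("binary", "survival"))
    msg <- c(msg, "invalid 'outcomeType'")
  cd <- colData(object)
  if (ncol(object) < 2L) msg <- c(msg, "at least 2 samples are required")
  if (identical(object@outcomeType, "binary")) {
    if (!"status" %in% colnames(cd)) msg <- c(msg, "colData lacks 'status'")
  } else {
    if (!all(c("time", "event") %in% colnames(cd)))
      msg <- c(msg, "colData lacks 'time'/'event'")
  }
  if (!all(object@clinicalCovariates %in% colnames(cd)))
    msg <- c(msg, "clinical covariate columns missing from colData")
  if (length(msg)) msg else TRUE
})

#' Penalty specification
#'
#' Captures the penalty family, the tuning parameter (a positive number, or
#' `NA` meaning "select by cross-validation"), adaptive weights, and features
#' carrying an infinite penalty (coefficient pinned at zero).
#'
#' @slot penalty `"ridge"`, `"lasso"` or `"adaptive_lasso"`.
#' @slot lambda positive numeric, or `NA_real_` for CV selection.
#' @slot weights named positive weights w_j (adaptive lasso only); the
#'   penalty applied to feature j is `lambda / w_j * |beta_j|`.
#' @slot excluded feature IDs with infinite penalty.
#' @export
setClass("PenaltySpec",
  slots = c(penalty = "character", lambda = "numeric", weights = "numeric",
            excluded = "character"))

setValidity("PenaltySpec", function(object) {
  msg <- character()
  if (!object@penalty %in% .PENALTIES) msg <- c(msg, "invalid 'penalty'")
  if (length(object@lambda) != 1L ||
      (!is.na(object@lambda) && object@lambda < 0))
    msg <- c(msg, "'lambda' must be a single non-negative number or NA (cv)")
  if (identical(object@penalty, "adaptive_lasso")) {
    if (!length(object@weights)) msg <- c(msg, "adaptive lasso requires weights")
    if (any(object@weights <= 0)) msg <- c(msg, "adaptive weights must be > 0")
    if (is.null(names(object@weights))) msg <- c(msg, "weights must be named")
  } else if (length(object@weights)) {
    msg <- c(msg, "weights are only meaningful for the adaptive lasso")
  }
  if (length(msg)) msg else TRUE
})

#' Penalized regression fit
#'
#' @slot family `"logistic"`, `"cox"` or `"gaussian"`.
#' @slot penalty penalty family used.
#' @slot intercept intercept on the original covariate scale (0 and
#'   inapplicable for Cox).
#' @slot coefficients named coefficient vector on the original scale.
#' @slot lambda tuning parameter actually used (internal 1/n-loss scale).
#' @slot objective value of the penalized objective at the solution.
#' @slot converged logical convergence flag.
#' @slot std internal standardization record (centers, scales).
#' @slot penaltyFactors internal per-feature penalty factors (Inf = excluded).
#' @slot nObs number of samples the fit used.
#' @export
setClass("PenalizedFit",
  slots = c(family = "character", penalty = "character",
            intercept = "numeric", coefficients = "numeric",
            lambda = "numeric", objective = "numeric", converged = "logical",
            std = "list", penaltyFactors = "numeric", nObs = "integer"))

#' Univariate screening result
#'
#' Per-feature univariate p-values, Benjamini-Hochberg adjusted q-values and
#' the selection indicator at the chosen FDR threshold. Degenerate or
#' non-converged univariate fits carry `NA` p-values, are excluded from the
#' multiplicity correction, and are never selected.
#'
#' @slot featureIDs feature identifiers.
#' @slot pValues two-sided Wald p-values (NA = flagged).
#' @slot qValues BH-adjusted values.
#' @slot selected logical selection indicator (`qValues <= qThreshold`).
#' @slot qThreshold the FDR threshold used.
#' @export
setClass("ScreenResult",
  slots = c(featureIDs = "character", pValues = "numeric", qValues = "numeric",
            selected = "logical", qThreshold = "numeric"))

#' Post-selection inference result
#'
#' @slot table data.frame with one row per selected feature: `featureID`,
#'   `coefficient`, `pValue`, `Vminus`, `Vplus`.
#' @slot lambda the fixed penalty level conditioned on.
#' @slot sigma plug-in noise scale of the working Gaussian problem.
#' @slot family model family of the underlying fit.
#' @export
setClass("SelectiveInferenceResult",
  slots = c(table = "data.frame", lambda = "numeric", sigma = "numeric",
            family = "character"))

#' Cross-validated prediction-power report
#'
#' @slot family model family evaluated.
#' @slot nFolds number of folds (1 means "not performed").
#' @slot performed logical; FALSE when nFolds = 1.
#' @slot perFold data.frame of per-fold metrics.
#' @slot aggregate named numeric vector of fold-averaged metrics, all kept on
#'   the \[0, 1\] scale (AUC is multiplied by 100 only for display).
#' @slot seed fold-assignment seed.
#' @slot threshold,thresholdScale classification rule used for the binary
#'   confusion metrics.
#' @export
setClass("CVReport",
  slots = c(family = "character", nFolds = "integer", performed = "logical",
            perFold = "data.frame", aggregate = "numeric", seed = "integer",
            threshold = "numeric", thresholdScale = "character"))

#' Multivariate model report
#'
#' One row per active feature with the coefficient and its exponentiated
#' effect size (hazard ratio for Cox, odds ratio for logistic).
#'
#' @slot family model family.
#' @slot table data.frame: `featureID`, `coefficient`, `effectSize`,
#'   `pValue` (NA when post-selection inference was not run).
#' @slot effectLabel `"hazard_ratio"` or `"odds_ratio"`.
#' @slot intercept model intercept (0 and inapplicable for Cox).
#' @slot threshold,thresholdScale classification rule attached to the model.
#' @export
setClass("ModelReport",
  slots = c(family = "character", table = "data.frame",
            effectLabel = "character", intercept = "numeric",
            threshold = "numeric", thresholdScale = "character"))
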