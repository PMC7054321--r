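#' Accessors for penomics objects
#'
#' Small accessor generics: `sampleIDs()`/`featureIDs()` return identifier
#' vectors; `covariates()` returns the samples x features numeric matrix;
#' `getOutcome()` rebuilds the outcome object from a [MolecularDataSet];
#' `activeSet()` lists features with nonzero coefficients; `isSelected()`,
#' `pValues()`, `qValues()` expose screening results; `aggregateMetrics()`
#' the fold-averaged metrics of a [CVReport]; `reportTable()` the per-feature
#' table of a [ModelReport] or [SelectiveInferenceResult].
#'
#' @param x a penomics object.
#' @param object a penomics object (for `coef`).
#' @param ... unused.
#' @return See the description for each accessor.
#' @name accessors
NULL

#' @rdname accessors
setMethod("sampleIDs", "MolecularMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIDs", "BinaryOutcome", function(x) x@sampleIDs)
#' @rdname accessors
setMethod("sampleIDs", "SurvivalOutcome", function(x) x@sampleIDs)
#' @rdname accessors
setMethod("sampleIDs", "MolecularDataSet", function(x) colnames(x))

#' @rdname accessors
setMethod("featureIDs", "MolecularMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("featureIDs", "MolecularDataSet", function(x) rownames(x))
#' @rdname accessors
setMethod("featureIDs", "ScreenResult", function(x) x@featureIDs)

#' @rdname accessors
setMethod("featureKind", "MolecularMatrix", function(x) x@kind)
#' @rdname accessors
setMethod("featureKind", "MolecularDataSet", function(x) x@featureKind)

#' @rdname accessors
setMethod("outcomeType", "MolecularDataSet", function(x) x@outcomeType)

#' @rdname accessors
setMethod("covariates", "MolecularMatrix", function(x) x@values)
#' @rdname accessors
setMethod("covariates", "MolecularDataSet",
  function(x) t(SummarizedExperiment::assay(x, "covariates")))

#' @rdname accessors
setMethod("getOutcome", "MolecularDataSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (identical(x@outcomeType, "binary")) {
    binaryOutcome(colnames(x), as.integer(cd$status),
                  positiveLabel = S4Vectors::metadata(x)$positiveLabel %||% "1")
  } else {
    survivalOutcome(colnames(x), as.numeric(cd$time), as.integer(cd$event))
  }
})

#' @rdname accessors
setMethod("activeSet", "PenalizedFit",
  function(x) names(x@coefficients)[x@coefficients != 0])

#' @rdname accessors
#' @export
setMethod("coef", "PenalizedFit", function(object, ...) object@coefficients)

#' @rdname accessors
setMethod("isSelected", "ScreenResult", function(x) x@selected)
#' @rdname accessors
setMethod("pValues", "ScreenResult", function(x) x@pValues)
#' @rdname accessors
setMethod("qValues", "ScreenResult", function(x) x@qValues)

#' @rdname accessors
setMethod("aggregateMetrics", "CVReport", function(x) x@aggregate)

#' @rdname accessors
setMethod("reportTable", "ModelReport", function(x) x@table)
#' @rdname accessors
setMethod("reportTable", "SelectiveInferenceResult", function(x) x@table)

#' Clinical covariate matrix of a dataset
#'
#' @param x a [MolecularDataSet].
#' @return numeric samples x covariates matrix, or NULL when the dataset has
#'   no clinical covariates.
#' @export
clinicalMatrix <- function(x) {
  stopifnot(is(x, "MolecularDataSet"))
  if (!length(x@clinicalCovariates)) return(NULL)
  cd <- SummarizedExperiment::colData(x)
  m <- as.matrix(as.data.frame(cd[, x@clinicalCovariates, drop = FALSE]))
  rownames(m) <- colnames(x)
  m
}

#' @exportMethod show
setMethod("show", "MolecularMatrix", function(object) {
  cat(sprintf("MolecularMatrix: %d samples x %d features (%s)\n",
              nrow(object@values), ncol(object@values), object@kind))
})

setMethod("show", "MolecularDataSet", function(object) {
  cat(sprintf("MolecularDataSet: %d features x %d samples (%s covariates, %s outcome)\n",
              nrow(object), ncol(object), object@featureKind, object@outcomeType))
  if (length(object@clinicalCovariates))
    cat("  clinical covariates:",
        paste(object@clinicalCovariates, collapse = ", "), "\n")
})

setMethod("show", "PenalizedFit", function(object) {
  cat(sprintf("PenalizedFit: %s family, %s penalty, lambda = %.4g\n",
              object@family, object@penalty, object@lambda))
  cat(sprintf("  %d/%d nonzero coefficients; converged: %s\n",
              sum(object@coefficients != 0), length(object@coefficients),
              object@converged))
})

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf("ScreenResult: %d features, %d selected at q <= %g\n",
              length(object@featureIDs), sum(object@selected),
              object@qThreshold))
})

setMethod("show", "CVReport", function(object) {
  if (!object@performed) {
    cat("CVReport: cross-validation not performed (1 fold requested)\n")
    return(invisible(NULL))
  }
  cat(sprintf("CVReport: %d-fold, %s family (seed %d)\n",
              object@nFolds, object@family, object@seed))
  agg <- object@aggregate
  for (nm in names(agg)) {
    shown <- if (identical(nm, "auc")) agg[[nm]] * 100 else agg[[nm]]
    cat(sprintf("  %s: %.3f\n", nm, shown))
  }
})

setMethod("show", "SelectiveInferenceResult", function(object) {
  cat(sprintf("SelectiveInferenceResult: %d features at lambda = %.4g\n",
              nrow(object@table), object@lambda))
  print(object@table, digits = 4)
})

setMethod("show", "ModelReport", function(object) {
  cat(sprintf("ModelReport (%s): %d features, threshold %g on %s scale\n",
              object@family, nrow(object@table), object@threshold,
              object@thresholdScale))
  tab <- object@table
  tab$coefficient <- round(tab$coefficient, 3)
  tab$effectSize <- round(tab$effectSize, 3)
  print(tab)
})
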