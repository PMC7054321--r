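#' Multivariate model report with exponentiated effect sizes
#'
#' One row per active feature with its coefficient and
#' `effectSize = exp(coefficient)` -- a hazard ratio for the Cox family, an
#' odds ratio for the logistic family. Full precision is retained in the
#' object; `show()` rounds to 3 decimals for display.
#'
#' @param fit a [PenalizedFit-class].
#' @param inference optional [SelectiveInferenceResult-class] whose p-values
#'   are joined by feature ID.
#' @param threshold,thresholdScale classification rule stored with the model
#'   (default 0.5 on the probability scale).
#' @return a [ModelReport-class].
#' @export
effectSizes <- function(fit, inference = NULL, threshold = 0.5,
                        thresholdScale = c("probability",
                                           "linear_predictor")) {
  stopifnot(is(fit, "PenalizedFit"))
  thresholdScale <- match.arg(thresholdScale)
  co <- fit@coefficients
  act <- co[co != 0]
  tab <- data.frame(featureID = names(act),
                    coefficient = unname(act),
                    effectSize = unname(exp(act)),
                    pValue = NA_real_, row.names = NULL)
  if (!is.null(inference)) {
    idx <- match(tab$featureID, inference@table$featureID)
    tab$pValue <- inference@table$pValue[idx]
  }
  new("ModelReport", family = fit@family, table = tab,
      effectLabel = if (identical(fit@family, "cox")) "hazard_ratio"
                    else "odds_ratio",
      intercept = if (identical(fit@family, "cox")) 0 else fit@intercept,
      threshold = threshold, thresholdScale = thresholdScale)
}

.modelParts <- function(model) {
  if (is(model, "ModelReport")) {
    list(intercept = model@intercept,
         coefficients = stats::setNames(model@table$coefficient,
                                        model@table$featureID),
         family = model@family)
  } else if (is(model, "PenalizedFit")) {
    co <- model@coefficients
    list(intercept = model@intercept, coefficients = co[co != 0],
         family = model@family)
  } else .err("penomics_domain", "need a ModelReport or PenalizedFit")
}

#' Linear predictor of a fitted model for new samples
#'
#' `intercept + sum_j coefficient_j * x_j`: the log-odds for a logistic
#' model, the log relative hazard for a Cox model. Every model feature must
#' be present in the new covariate data.
#'
#' @param model a [ModelReport-class] or [PenalizedFit-class].
#' @param xNew named numeric vector, or a matrix / data.frame with one row
#'   per sample and features in columns.
#' @return numeric vector of scores, one per sample.
#' @export
linearPredictor <- function(model, xNew) {
  mp <- .modelParts(model)
  if (is.null(dim(xNew))) xNew <- t(as.matrix(xNew))
  xNew <- as.matrix(xNew)
  need <- names(mp$coefficients)
  miss <- setdiff(need, colnames(xNew))
  if (length(miss))
    .err("penomics_missing_feature", "missing model feature(s): %s",
         paste(miss, collapse = ", "))
  drop(mp$intercept + xNew[, need, drop = FALSE] %*% mp$coefficients)
}

#' Classify new samples with a fitted binary model
#'
#' A sample is classified 1 exactly when its score is strictly greater than
#' the threshold on the declared scale: the fitted probability for
#' `scale = "probability"`, the linear predictor (log-odds) for
#' `scale = "linear_predictor"`. A score equal to the threshold yields 0.
#'
#' @inheritParams linearPredictor
#' @param threshold finite classification threshold.
#' @param scale `"probability"` or `"linear_predictor"`.
#' @return integer vector of 0/1 classes.
#' @export
classifySamples <- function(model, xNew, threshold = 0.5,
                            scale = c("probability", "linear_predictor")) {
  scale <- match.arg(scale)
  if (!is.finite(threshold)) .err("penomics_domain", "non-finite threshold")
  lp <- linearPredictor(model, xNew)
  score <- if (identical(scale, "probability")) .expit(lp) else lp
  as.integer(score > threshold)
}
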