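#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) sample pairs in which the positive
#' sample scores strictly higher, counting ties as 1/2. Invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores numeric scores (any monotone scale: probability, log-odds).
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    .err("penomics_degenerate", "both classes are required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy, sensitivity and specificity at a threshold
#'
#' A sample is predicted positive iff its score is strictly greater than the
#' threshold; `scores` must already be on the declared `thresholdScale`.
#' Sensitivity is TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n.
#' With no positive (or negative) labels the undefined metric is returned as
#' `NA`.
#'
#' @param scores numeric scores on the `thresholdScale` scale.
#' @param labels 0/1 labels.
#' @param threshold finite classification threshold.
#' @param thresholdScale `"probability"` or `"linear_predictor"`; recorded
#'   scale of `scores` and `threshold`.
#' @return named numeric vector: accuracy, sensitivity, specificity.
#' @export
confusionMetrics <- function(scores, labels, threshold = 0.5,
                             thresholdScale = c("probability",
                                                "linear_predictor")) {
  thresholdScale <- match.arg(thresholdScale)
  if (!is.finite(threshold)) .err("penomics_domain", "non-finite threshold")
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L); fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L); fp <- sum(pred == 1L & labels == 0L)
  c(accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Harrell's concordance index
#'
#' Over ordered pairs (i, j) in which subject i is usable as the earlier
#' subject -- `event_i = 1` and `time_i < time_j`, or `event_i = 1`,
#' `time_i = time_j` and `event_j = 0` -- the pair is concordant when
#' `risk_i > risk_j`; tied risks count 1/2.
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param risk numeric risk scores (higher = earlier expected event).
#' @return concordance in \[0, 1\].
#' @export
cIndex <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  event <- as.integer(event)
  comp <- outer(seq_len(n), seq_len(n), function(i, j) {
    (event[i] == 1L) & (time[i] < time[j] |
                        (time[i] == time[j] & event[j] == 0L))
  })
  diag(comp) <- FALSE
  nComp <- sum(comp)
  if (nComp == 0L)
    .err("penomics_degenerate", "no comparable pairs for the C-index")
  rdiff <- outer(risk, risk, function(a, b) (a > b) + 0.5 * (a == b))
  sum(rdiff[comp]) / nComp
}

#' Cross-validated prediction power of the configured pipeline
#'
#' For each of `nFolds` stratified folds the entire configured pipeline --
#' optional FDR screening, tuning-CV of lambda, penalized fitting (with the
#' two-stage refit for the adaptive lasso) -- is run on the training portion
#' only, and the held-out portion is scored: accuracy / sensitivity /
#' specificity / AUC for the logistic family, Harrell's C-index for Cox.
#' Aggregate metrics are unweighted means over folds. With `nFolds = 1` no
#' cross-validation is performed and the report says so.
#'
#' @param data a [MolecularDataSet-class].
#' @param nFolds number of folds (default 5; 1 disables CV).
#' @param seed fold-assignment seed (all randomness derives from it).
#' @param screen run univariate FDR screening inside each training fold.
#' @param q FDR threshold for screening.
#' @param penalty,lambda,nFoldsTune,standardize,includeClinical passed to
#'   [penalizedFit()] (per training fold).
#' @param threshold,thresholdScale classification rule for the binary
#'   confusion metrics (default 0.5 on the probability scale).
#' @param pool aggregate by pooling all held-out predictions into one
#'   metric computation instead of averaging per-fold metrics (default
#'   FALSE: unweighted mean over folds; per-fold rows are reported either
#'   way).
#' @return a [CVReport-class].
#' @export
kfoldCV <- function(data, nFolds = 5, seed = 1, screen = FALSE, q = 0.05,
                    penalty = "lasso", lambda = "cv", nFoldsTune = 10,
                    standardize = NULL, includeClinical = FALSE,
                    threshold = 0.5,
                    thresholdScale = c("probability", "linear_predictor"),
                    pool = FALSE) {
  stopifnot(is(data, "MolecularDataSet"))
  thresholdScale <- match.arg(thresholdScale)
  family <- .familyOf(data)
  if (nFolds == 1) {
    return(new("CVReport", family = family, nFolds = 1L, performed = FALSE,
               perFold = data.frame(), aggregate = numeric(),
               seed = as.integer(seed), threshold = threshold,
               thresholdScale = thresholdScale))
  }
  n <- ncol(data)
  if (nFolds < 1 || nFolds > n)
    .err("penomics_domain", "'nFolds' must lie in 1..n_samples")
  ydata <- .ydataOf(data)
  strata <- if (identical(family, "logistic")) ydata$y else ydata$event
  folds <- .makeFolds(strata, nFolds, seed)
  if (identical(family, "logistic")) {
    for (k in seq_len(nFolds)) {
      if (length(unique(ydata$y[folds == k])) < 2L)
        .err("penomics_fold",
             "fold %d holds a single outcome class even after stratification", k)
    }
  }
  rows <- vector("list", nFolds)
  pooled <- list(scores = c(), y = c(), time = c(), event = c())
  for (k in seq_len(nFolds)) {
    tr <- folds != k
    dTrain <- data[, tr]
    dTest <- data[, !tr]
    model <- .trainPipeline(dTrain, screen = screen, q = q, penalty = penalty,
                            lambda = lambda, nFoldsTune = nFoldsTune,
                            standardize = standardize,
                            includeClinical = includeClinical,
                            seed = seed + k)
    sc <- .scoreSamples(model, dTest, includeClinical)
    if (identical(family, "logistic")) {
      yTe <- .ydataOf(dTest)$y
      pooled$scores <- c(pooled$scores, sc); pooled$y <- c(pooled$y, yTe)
      thrScores <- if (identical(thresholdScale, "probability"))
        .expit(sc) else sc
      cm <- confusionMetrics(thrScores, yTe, threshold, thresholdScale)
      rows[[k]] <- data.frame(fold = k, accuracy = cm[["accuracy"]],
                              sensitivity = cm[["sensitivity"]],
                              specificity = cm[["specificity"]],
                              auc = aucScore(sc, yTe),
                              nSelected = model$nSelected)
    } else {
      yTe <- .ydataOf(dTest)
      pooled$scores <- c(pooled$scores, sc)
      pooled$time <- c(pooled$time, yTe$time)
      pooled$event <- c(pooled$event, yTe$event)
      ci <- tryCatch(cIndex(yTe$time, yTe$event, sc),
                     error = function(e) NA_real_)
      rows[[k]] <- data.frame(fold = k, c_index = ci,
                              nSelected = model$nSelected)
    }
  }
  perFold <- do.call(rbind, rows)
  metricCols <- setdiff(colnames(perFold), c("fold", "nSelected"))
  agg <- if (pool) {
    # one metric computation over all held-out predictions
    if (identical(family, "logistic")) {
      thr <- if (identical(thresholdScale, "probability"))
        .expit(pooled$scores) else pooled$scores
      cm <- confusionMetrics(thr, pooled$y, threshold, thresholdScale)
      c(cm, auc = aucScore(pooled$scores, pooled$y))
    } else {
      c(c_index = cIndex(pooled$time, pooled$event, pooled$scores))
    }
  } else {
    vapply(perFold[metricCols], mean, numeric(1), na.rm = TRUE)
  }
  new("CVReport", family = family, nFolds = as.integer(nFolds),
      performed = TRUE, perFold = perFold, aggregate = agg,
      seed = as.integer(seed), threshold = threshold,
      thresholdScale = thresholdScale)
}

# Train the configured pipeline on a training dataset; returns a scoring
# model (intercept + coefficients) robust to empty screening / empty active
# sets (falls back to the intercept-only / null-risk model).
.trainPipeline <- function(dTrain, screen, q, penalty, lambda, nFoldsTune,
                           standardize, includeClinical, seed) {
  family <- .familyOf(dTrain)
  nullModel <- list(
    family = family,
    intercept = if (identical(family, "logistic"))
      .logit(min(max(mean(.ydataOf(dTrain)$y), 1e-6), 1 - 1e-6)) else 0,
    coefficients = numeric(), nSelected = 0L)
  if (screen) {
    sr <- screenFeatures(dTrain, q = q, includeClinical = includeClinical)
    if (!any(sr@selected)) return(nullModel)
    dTrain <- applyScreen(dTrain, sr)
  }
  fit <- tryCatch({
    if (identical(penalty, "adaptive_lasso")) {
      first <- penalizedFit(dTrain, penalty = "lasso", lambda = lambda,
                            standardize = standardize,
                            includeClinical = includeClinical,
                            nFoldsTune = nFoldsTune, seed = seed)
      spec <- adaptiveWeights(first)
      penalizedFit(dTrain, penalty = "adaptive_lasso", lambda = lambda,
                   weights = spec@weights, excluded = spec@excluded,
                   standardize = standardize,
                   includeClinical = includeClinical,
                   nFoldsTune = nFoldsTune, seed = seed)
    } else {
      penalizedFit(dTrain, penalty = penalty, lambda = lambda,
                   standardize = standardize,
                   includeClinical = includeClinical,
                   nFoldsTune = nFoldsTune, seed = seed)
    }
  }, penomics_nothing_to_refit = function(e) NULL,
     penomics_degenerate = function(e) NULL)
  if (is.null(fit)) return(nullModel)
  co <- fit@coefficients
  list(family = family, intercept = fit@intercept,
       coefficients = co[co != 0],
       nSelected = sum(co[setdiff(names(co), fit@std$clinical)] != 0))
}

.scoreSamples <- function(model, dTest, includeClinical) {
  X <- .designMatrix(dTest, includeClinical)
  lp <- rep(model$intercept, ncol(dTest))
  if (length(model$coefficients)) {
    feats <- names(model$coefficients)
    lp <- lp + drop(X[, feats, drop = FALSE] %*% model$coefficients)
  }
  lp
}
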