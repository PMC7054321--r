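#' Seeded synthetic molecular datasets
#'
#' Generates covariate matrices with the statistical structure the pipeline
#' assumes and outcomes from sparse generalized linear / proportional-
#' hazards models, together with a ground-truth record:
#' \itemize{
#'   \item `featureModel = "binary"`: independent 0/1 alteration indicators
#'     with per-feature prevalence drawn once from `prevalenceRange`
#'     (default 1--10\%, the typical per-gene mutation prevalence) or fixed
#'     via `prevalence`;
#'   \item `featureModel = "zscore"`: independent standard-normal expression
#'     Z-scores, so ~4.6\% of entries are "abnormal" at the usual |Z| > 2
#'     rule;
#'   \item `outcomeModel = "logistic"`: y ~ Bernoulli(expit(intercept +
#'     x beta));
#'   \item `outcomeModel = "cox"`: event times from an exponential
#'     proportional-hazards model `h(t|x) = baselineRate * exp(x beta)` with
#'     independent exponential censoring at `censoringRate` (default tuned
#'     to ~30\% censoring under the null: `baselineRate * 3/7`).
#' }
#'
#' @param nSamples,nFeatures dimensions.
#' @param support integer indices of truly associated features.
#' @param coefficients their true coefficients (same length as `support`).
#' @param featureModel `"binary"` or `"zscore"`.
#' @param outcomeModel `"logistic"` or `"cox"`.
#' @param prevalence optional fixed per-feature prevalence(s) (recycled).
#' @param prevalenceRange range to draw per-feature prevalences from.
#' @param intercept logistic intercept.
#' @param baselineRate exponential baseline hazard rate.
#' @param censoringRate exponential censoring rate.
#' @param seed integer seed; the same seed reproduces the dataset bit for
#'   bit.
#' @return a [MolecularDataSet-class]; `metadata(ds)$groundTruth` records
#'   the support (feature IDs), coefficients, and achieved censoring
#'   fraction (Cox).
#' @importFrom stats rbinom rnorm rexp runif
#' @export
simulateDataset <- function(nSamples, nFeatures, support = integer(),
                            coefficients = numeric(),
                            featureModel = c("binary", "zscore"),
                            outcomeModel = c("logistic", "cox"),
                            prevalence = NULL,
                            prevalenceRange = c(0.01, 0.10),
                            intercept = 0, baselineRate = 0.1,
                            censoringRate = NULL, seed = 1) {
  featureModel <- match.arg(featureModel)
  outcomeModel <- match.arg(outcomeModel)
  stopifnot(length(support) == length(coefficients))
  if (length(support) && (min(support) < 1 || max(support) > nFeatures))
    .err("penomics_domain", "'support' indices out of range")
  sampleIDs <- sprintf("S%04d", seq_len(nSamples))
  featIDs <- sprintf("g%04d", seq_len(nFeatures))
  .withSeed(seed, {
    if (identical(featureModel, "binary")) {
      prev <- if (!is.null(prevalence)) rep_len(prevalence, nFeatures)
              else runif(nFeatures, prevalenceRange[1], prevalenceRange[2])
      if (any(prev <= 0 | prev >= 1))
        .err("penomics_domain", "prevalences must lie in (0, 1)")
      X <- vapply(prev, function(p) rbinom(nSamples, 1L, p),
                  numeric(nSamples))
      kind <- "binary"
    } else {
      X <- matrix(rnorm(nSamples * nFeatures), nSamples, nFeatures)
      kind <- "zscore"
    }
    dimnames(X) <- list(sampleIDs, featIDs)
    lp <- if (length(support))
      drop(X[, support, drop = FALSE] %*% coefficients) else rep(0, nSamples)
    if (identical(outcomeModel, "logistic")) {
      y <- rbinom(nSamples, 1L, .expit(intercept + lp))
      if (length(unique(y)) < 2L)
        .err("penomics_degenerate",
             "simulated outcome is single-class; adjust intercept/effects")
      outcome <- binaryOutcome(sampleIDs, y)
    } else {
      if (baselineRate <= 0) .err("penomics_domain", "baselineRate must be > 0")
      cr <- censoringRate %||% (baselineRate * 3 / 7)
      if (cr < 0) .err("penomics_domain", "censoringRate must be >= 0")
      tEvent <- rexp(nSamples, rate = baselineRate * exp(lp))
      tCens <- if (cr > 0) rexp(nSamples, rate = cr) else rep(Inf, nSamples)
      ev <- as.integer(tEvent < tCens)
      if (!any(ev == 1L))
        .err("penomics_degenerate", "no events under the given rates")
      outcome <- survivalOutcome(sampleIDs, pmin(tEvent, tCens), ev)
    }
    M <- molecularMatrix(X, kind)
    ds <- alignDataset(M, outcome)
    S4Vectors::metadata(ds)$groundTruth <- list(
      support = featIDs[support],
      coefficients = stats::setNames(coefficients, featIDs[support]),
      censoringFraction = if (identical(outcomeModel, "cox"))
        mean(outcome@event == 0L) else NA_real_,
      seed = seed)
    ds
  })
}

#' Achieved censoring fraction of a survival dataset
#'
#' @param data a [MolecularDataSet-class] with a survival outcome.
#' @return fraction of censored (event = 0) samples, in \[0, 1\].
#' @export
achievedCensoring <- function(data) {
  stopifnot(is(data, "MolecularDataSet"))
  if (!identical(outcomeType(data), "survival"))
    .err("penomics_domain", "achievedCensoring needs a survival outcome")
  mean(.ydataOf(data)$event == 0)
}

#' Write a simulated dataset to delimited text files
#'
#' Emits the covariate matrix (`matrix.tsv`), the clinical table
#' (`clinical.tsv`) and, when present, the ground-truth sidecar
#' (`ground_truth.json`).
#'
#' @param data a [MolecularDataSet-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(data, dir) {
  stopifnot(is(data, "MolecularDataSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mPath <- file.path(dir, "matrix.tsv")
  writeMolecularMatrix(molecularMatrix(covariates(data),
                                       kind = featureKind(data)), mPath)
  cd <- as.data.frame(SummarizedExperiment::colData(data))
  clin <- data.frame(sample_id = colnames(data), cd, check.names = FALSE)
  cPath <- file.path(dir, "clinical.tsv")
  utils::write.table(clin, cPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(mPath, cPath)
  gt <- S4Vectors::metadata(data)$groundTruth
  if (!is.null(gt)) {
    gPath <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(gt, gPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, gPath)
  }
  invisible(paths)
}
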