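#' Construct a MolecularMatrix
#'
#' @param values numeric samples x features matrix with row (sample) and
#'   column (feature) names.
#' @param kind `"zscore"` for continuous expression Z-scores or `"binary"`
#'   for 0/1 alteration indicators.
#' @return a [MolecularMatrix-class].
#' @export
molecularMatrix <- function(values, kind = c("zscore", "binary")) {
  kind <- match.arg(kind)
  new("MolecularMatrix", values = values, kind = kind)
}

#' @rdname binaryOutcome
#' @export
binaryOutcome <- function(sampleIDs, y, positiveLabel = "1") {
  new("BinaryOutcome", sampleIDs = as.character(sampleIDs),
      y = as.integer(y), positiveLabel = positiveLabel)
}

#' Outcome constructors
#'
#' `binaryOutcome()` wraps a 0/1 outcome; `survivalOutcome()` wraps a
#' right-censored survival outcome (observed time and 0/1 event indicator).
#'
#' @param sampleIDs character sample identifiers.
#' @param y 0/1 outcome values.
#' @param positiveLabel what y = 1 means.
#' @param time non-negative observed times.
#' @param event 0/1 event indicators (1 = event observed, 0 = censored).
#' @return a [BinaryOutcome-class] or [SurvivalOutcome-class].
#' @name binaryOutcome
#' @export
survivalOutcome <- function(sampleIDs, time, event) {
  new("SurvivalOutcome", sampleIDs = as.character(sampleIDs),
      time = as.numeric(time), event = as.integer(event))
}

.detectDelimiter <- function(path) {
  line <- readLines(path, n = 1L)
  if (!length(line)) .err("penomics_malformed_header", "empty file: %s", path)
  nTab <- lengths(regmatches(line, gregexpr("\t", line)))
  nCom <- lengths(regmatches(line, gregexpr(",", line)))
  if (nTab == 0 && nCom == 0)
    .err("penomics_malformed_header",
         "cannot auto-detect delimiter in %s (no tab or comma in header)", path)
  if (nTab >= nCom) "\t" else ","
}

#' Read a delimited molecular matrix
#'
#' Expects a header row of feature IDs and a first column of sample IDs
#' (samples in rows). Tab and comma delimiters are auto-detected; anything
#' else must be passed explicitly.
#'
#' @param path file path.
#' @param delimiter `"auto"` (default), or an explicit single character.
#' @param kind `"zscore"` or `"binary"`.
#' @param dropMissingFeatures drop features containing missing cells instead
#'   of raising an error (default FALSE: missingness is an error).
#' @return a [MolecularMatrix-class].
#' @export
readMolecularMatrix <- function(path, delimiter = "auto",
                                kind = c("zscore", "binary"),
                                dropMissingFeatures = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .err("penomics_io", "file not found: %s", path)
  sep <- if (identical(delimiter, "auto")) .detectDelimiter(path) else delimiter
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL,
                          colClasses = NA)
  if (ncol(df) < 2L)
    .err("penomics_malformed_header",
         "matrix file needs a sample-ID column plus >= 1 feature column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    .err("penomics_duplicate_ids", "duplicated sample IDs: %s",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  feats <- colnames(df)[-1L]
  if (anyDuplicated(feats))
    .err("penomics_duplicate_ids", "duplicated feature IDs: %s",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  vals <- df[-1L]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    # read.table leaves non-numeric cells as character columns
    .err("penomics_non_numeric", "non-numeric cells in feature(s): %s",
         paste(feats[bad], collapse = ", "))
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, feats)
  if (anyNA(m)) {
    if (dropMissingFeatures) {
      keep <- colSums(is.na(m)) == 0L
      if (!any(keep))
        .err("penomics_missing_values", "all features contain missing cells")
      m <- m[, keep, drop = FALSE]
    } else {
      .err("penomics_missing_values",
           "missing cells present; set dropMissingFeatures = TRUE to drop them")
    }
  }
  if (identical(kind, "binary") && !all(m %in% c(0, 1)))
    .err("penomics_binary_domain",
         "binary matrix contains values outside {0, 1}")
  molecularMatrix(m, kind)
}

#' Write a molecular matrix to delimited text
#'
#' @param M a [MolecularMatrix-class].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @return the path, invisibly.
#' @export
writeMolecularMatrix <- function(M, path, delimiter = "\t") {
  stopifnot(is(M, "MolecularMatrix"))
  # %.17g keeps the full double precision so a read-back is bit-exact
  txt <- apply(M@values, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(M@values))
  df <- data.frame(sample_id = rownames(M@values), txt, check.names = FALSE)
  colnames(df) <- c("sample_id", colnames(M@values))
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dichotomize expression Z-scores into abnormality indicators
#'
#' An entry is abnormal (coded 1) when its Z-score lies strictly beyond the
#' cutoff in either direction, i.e. |z| > cutoff; z equal to the cutoff is
#' normal.
#'
#' @param M a [MolecularMatrix-class] of kind `"zscore"`.
#' @param cutoff positive abnormality cutoff (default 2).
#' @return a [MolecularMatrix-class] of kind `"binary"` with identical
#'   dimensions and dimnames.
#' @export
binarizeZscores <- function(M, cutoff = 2) {
  stopifnot(is(M, "MolecularMatrix"))
  if (!identical(M@kind, "zscore"))
    .err("penomics_kind", "binarizeZscores expects a zscore matrix")
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0)
    .err("penomics_domain", "'cutoff' must be a single positive number")
  out <- (abs(M@values) > cutoff) + 0
  dimnames(out) <- dimnames(M@values)
  molecularMatrix(out, "binary")
}

#' Filter features by alteration prevalence
#'
#' Keeps exactly the features altered (value 1) in at least `minFraction` of
#' samples; feature order is preserved. Typical choices: 0.01 for mutation
#' indicators, 0.02 for expression abnormality indicators.
#'
#' @param M a binary [MolecularMatrix-class].
#' @param minFraction minimum fraction of altered samples, in (0, 1].
#' @return a filtered [MolecularMatrix-class].
#' @export
prevalenceFilter <- function(M, minFraction) {
  stopifnot(is(M, "MolecularMatrix"))
  if (!identical(M@kind, "binary"))
    .err("penomics_kind", "prevalenceFilter expects a binary matrix")
  if (length(minFraction) != 1L || minFraction <= 0 || minFraction > 1)
    .err("penomics_domain", "'minFraction' must lie in (0, 1]")
  keep <- colMeans(M@values) >= minFraction
  if (!any(keep))
    .err("penomics_empty_filter",
         "no feature reaches prevalence %g; downstream fits are impossible",
         minFraction)
  molecularMatrix(M@values[, keep, drop = FALSE], "binary")
}

#' Align a molecular matrix with an outcome into an analysis dataset
#'
#' Restricts all components to the intersection of their sample IDs (in the
#' matrix's order) and assembles a [MolecularDataSet-class]. Dropped IDs are
#' recorded in `metadata(ds)$dropped`.
#'
#' @param M a [MolecularMatrix-class].
#' @param outcome a [BinaryOutcome-class] or [SurvivalOutcome-class].
#' @param clinical optional data.frame of numeric clinical covariates with
#'   rownames = sample IDs (included unpenalized downstream when configured).
#' @return a [MolecularDataSet-class].
#' @export
alignDataset <- function(M, outcome, clinical = NULL) {
  stopifnot(is(M, "MolecularMatrix"))
  oIDs <- sampleIDs(outcome)
  common <- intersect(rownames(M@values), oIDs)
  if (!length(common))
    .err("penomics_no_overlap", "no sample IDs shared between matrix and outcome")
  keep <- rownames(M@values)[rownames(M@values) %in% common]
  dropped <- list(matrix = setdiff(rownames(M@values), common),
                  outcome = setdiff(oIDs, common))
  vals <- M@values[keep, , drop = FALSE]
  oIdx <- match(keep, oIDs)
  if (is(outcome, "BinaryOutcome")) {
    y <- outcome@y[oIdx]
    if (anyNA(y)) .err("penomics_missing_outcome", "missing outcome values")
    cd <- S4Vectors::DataFrame(status = y, row.names = keep)
    type <- "binary"
    posLabel <- outcome@positiveLabel
  } else if (is(outcome, "SurvivalOutcome")) {
    tm <- outcome@time[oIdx]; ev <- outcome@event[oIdx]
    if (anyNA(tm) || anyNA(ev))
      .err("penomics_missing_outcome", "missing outcome values")
    cd <- S4Vectors::DataFrame(time = tm, event = ev, row.names = keep)
    type <- "survival"
    posLabel <- "1"
  } else .err("penomics_domain", "unsupported outcome class")
  clinCols <- character()
  if (!is.null(clinical)) {
    if (is.null(rownames(clinical)))
      .err("penomics_domain", "clinical table needs sample IDs as rownames")
    miss <- setdiff(keep, rownames(clinical))
    if (length(miss))
      .err("penomics_missing_outcome",
           "clinical covariates missing for sample(s): %s",
           paste(utils::head(miss, 5), collapse = ", "))
    cl <- clinical[keep, , drop = FALSE]
    if (!all(vapply(cl, is.numeric, logical(1))))
      .err("penomics_non_numeric", "clinical covariates must be numeric")
    if (anyNA(cl)) .err("penomics_missing_values",
                        "missing clinical covariate values")
    for (nm in colnames(cl)) cd[[nm]] <- cl[[nm]]
    clinCols <- colnames(cl)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(covariates = t(vals)),
    colData = cd)
  ds <- new("MolecularDataSet", se, featureKind = M@kind,
            outcomeType = type, clinicalCovariates = clinCols)
  S4Vectors::metadata(ds)$dropped <- dropped
  S4Vectors::metadata(ds)$positiveLabel <- posLabel
  ds
}

#' Read a clinical table
#'
#' The table must contain a `sample_id` column and either a 0/1 `status`
#' column (binary outcome) or `time` + 0/1 `event` columns (survival
#' outcome). Any remaining numeric columns are returned as clinical
#' covariates.
#'
#' @param path file path (TSV or CSV; auto-detected or explicit).
#' @param delimiter `"auto"` or an explicit separator.
#' @return a list with elements `outcome` (a [BinaryOutcome-class] or
#'   [SurvivalOutcome-class]) and `clinical` (data.frame or NULL).
#' @export
readClinicalTable <- function(path, delimiter = "auto") {
  if (!file.exists(path)) .err("penomics_io", "file not found: %s", path)
  sep <- if (identical(delimiter, "auto")) .detectDelimiter(path) else delimiter
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df))
    .err("penomics_malformed_header", "clinical table lacks 'sample_id'")
  ids <- as.character(df$sample_id)
  if ("status" %in% colnames(df)) {
    outcome <- binaryOutcome(ids, df$status)
    used <- c("sample_id", "status")
  } else if (all(c("time", "event") %in% colnames(df))) {
    outcome <- survivalOutcome(ids, df$time, df$event)
    used <- c("sample_id", "time", "event")
  } else {
    .err("penomics_malformed_header",
         "clinical table needs 'status' or 'time'+'event' columns")
  }
  rest <- df[, setdiff(colnames(df), used), drop = FALSE]
  clinical <- NULL
  if (ncol(rest)) {
    num <- vapply(rest, is.numeric, logical(1))
    if (any(num)) {
      clinical <- rest[, num, drop = FALSE]
      rownames(clinical) <- ids
    }
  }
  list(outcome = outcome, clinical = clinical)
}
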