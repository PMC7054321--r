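#' Univariate association p-values per feature
#'
#' Fits a single-covariate model per feature -- logistic regression with
#' intercept for a binary outcome, Cox regression for a survival outcome --
#' and returns the two-sided Wald p-value of the feature coefficient.
#' Zero-variance features and degenerate fits (non-convergence, perfect
#' separation, diverging standard errors) are flagged with `NA`; they are
#' excluded from the multiplicity correction and never selected.
#'
#' @param data a [MolecularDataSet-class].
#' @param includeClinical adjust every univariate model for the dataset's
#'   clinical covariates (default FALSE).
#' @return named numeric vector of p-values (NA = flagged).
#' @importFrom stats glm binomial pnorm coef var
#' @importFrom survival coxph Surv
#' @export
univariatePvalues <- function(data, includeClinical = FALSE) {
  stopifnot(is(data, "MolecularDataSet"))
  X <- covariates(data)
  cl <- if (includeClinical) clinicalMatrix(data) else NULL
  family <- .familyOf(data)
  ydata <- .ydataOf(data)
  p <- ncol(X)
  out <- rep(NA_real_, p)
  names(out) <- colnames(X)
  for (j in seq_len(p)) {
    x <- X[, j]
    if (var(x) == 0) next
    df <- data.frame(x = x)
    if (!is.null(cl)) df <- cbind(df, as.data.frame(cl))
    sep <- FALSE
    muffle <- function(w) {
      # perfect separation shows up as this glm warning; everything else
      # (step-halving notes etc.) is muffled and judged by the estimates
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
    pj <- tryCatch({
      if (identical(family, "logistic")) {
        df$y <- ydata$y
        fit <- withCallingHandlers(
          glm(y ~ ., data = df, family = binomial()), warning = muffle)
        sm <- summary(fit)$coefficients
        est <- sm["x", "Estimate"]; se <- sm["x", "Std. Error"]
        if (sep || !fit$converged || !is.finite(se) || se > 1e3 ||
            abs(est) > 15) NA_real_
        else 2 * pnorm(-abs(est / se))
      } else {
        df$time <- ydata$time; df$event <- ydata$event
        fit <- withCallingHandlers(
          coxph(Surv(time, event) ~ . - time - event, data = df),
          warning = muffle)
        est <- coef(fit)[["x"]]
        se <- sqrt(diag(fit$var))[[1L]]
        if (!is.finite(est) || !is.finite(se) || se > 1e3 || abs(est) > 15)
          NA_real_
        else 2 * pnorm(-abs(est / se))
      }
    }, error = function(e) NA_real_)
    out[j] <- pj
  }
  out
}

#' Benjamini-Hochberg selection
#'
#' Step-up FDR control: with the m non-missing p-values sorted ascending,
#' find the largest i with `p_(i) <= i * q / m` and select every feature
#' with a p-value at or below that cutoff. The reported q-values are the
#' standard BH-adjusted values (running minimum of `m * p_(i) / i` from the
#' largest rank down, capped at 1); selection is equivalently
#' `q_value <= q`. Missing p-values are excluded from m and never selected.
#'
#' @param pValues numeric p-values in \[0, 1\] (NA allowed), named by feature.
#' @param q FDR threshold in (0, 1), default 0.05.
#' @param featureIDs feature identifiers (defaults to `names(pValues)`).
#' @return a [ScreenResult-class].
#' @importFrom stats p.adjust
#' @export
bhSelect <- function(pValues, q = 0.05, featureIDs = names(pValues)) {
  if (length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    .err("penomics_domain", "'q' must lie strictly inside (0, 1)")
  ok <- !is.na(pValues)
  if (any(pValues[ok] < 0 | pValues[ok] > 1))
    .err("penomics_domain", "p-values must lie in [0, 1]")
  if (is.null(featureIDs)) featureIDs <- sprintf("f%d", seq_along(pValues))
  qv <- rep(NA_real_, length(pValues))
  qv[ok] <- p.adjust(pValues[ok], method = "BH")
  sel <- !is.na(qv) & qv <= q
  new("ScreenResult", featureIDs = featureIDs,
      pValues = as.numeric(pValues), qValues = qv, selected = sel,
      qThreshold = q)
}

#' Univariate screening with FDR control
#'
#' Convenience wrapper: [univariatePvalues()] followed by [bhSelect()].
#'
#' @inheritParams univariatePvalues
#' @inheritParams bhSelect
#' @return a [ScreenResult-class].
#' @export
screenFeatures <- function(data, q = 0.05, includeClinical = FALSE) {
  bhSelect(univariatePvalues(data, includeClinical = includeClinical), q = q)
}

#' Restrict a dataset to screened features
#'
#' @param data a [MolecularDataSet-class].
#' @param screen a [ScreenResult-class] computed on the same features.
#' @return the dataset restricted to the selected features.
#' @export
applyScreen <- function(data, screen) {
  stopifnot(is(data, "MolecularDataSet"), is(screen, "ScreenResult"))
  keep <- screen@featureIDs[screen@selected]
  if (!length(keep))
    .err("penomics_empty_screen", "no features passed screening")
  data[keep, ]
}
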