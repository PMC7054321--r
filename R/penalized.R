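#' @useDynLib penomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- family internals -------------------------------------------------
## ydata is list(y=) for logistic/gaussian, list(time=, event=) for cox.
## All losses below are the *unscaled* negative log-(partial-)likelihood;
## the penalized objective divides by n.

.nllLogistic <- function(y, eta) {
  # -sum(y*eta - log(1+exp(eta))), computed stably
  sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
}

# Breslow-ties log partial likelihood
.coxPL <- function(time, event, eta) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; eta_s <- eta[ord]
  m <- max(eta_s)                         # stabilize exp
  r_s <- exp(eta_s - m)
  Srev <- rev(cumsum(rev(r_s)))
  firstIdx <- match(t_s, t_s)             # first position of each tied time
  S_at <- Srev[firstIdx]
  ev <- e_s == 1
  sum(eta_s[ev]) - sum(log(S_at[ev]) + m)
}

# Score residuals u, diagonal-Hessian weights w and working response z for
# the Breslow partial likelihood at linear predictor eta.
.coxWork <- function(time, event, eta) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; eta_s <- eta[ord]
  m <- max(eta_s)
  r_s <- exp(eta_s - m)
  Srev <- rev(cumsum(rev(r_s)))
  firstIdx <- match(t_s, t_s)
  lastIdx <- n + 1L - match(t_s, rev(t_s))
  S_at <- Srev[firstIdx]
  c1 <- ifelse(e_s == 1, 1 / S_at, 0)
  c2 <- ifelse(e_s == 1, 1 / S_at^2, 0)
  A <- cumsum(c1)[lastIdx]
  B <- cumsum(c2)[lastIdx]
  u_s <- e_s - r_s * A
  w_s <- r_s * A - r_s^2 * B
  u <- numeric(n); w <- numeric(n)
  u[ord] <- u_s; w[ord] <- w_s
  wfl <- pmax(w, 1e-5)
  list(u = u, w = wfl, z = eta + u / wfl,
       nll = -.coxPL(time, event, eta))
}

.workingResponse <- function(family, ydata, eta) {
  switch(family,
    logistic = {
      p <- .expit(eta)
      w <- pmax(p * (1 - p), 1e-5)
      list(w = w, z = eta + (ydata$y - p) / w,
           nll = .nllLogistic(ydata$y, eta))
    },
    gaussian = list(w = rep(1, length(eta)), z = ydata$y,
                    nll = 0.5 * sum((ydata$y - eta)^2)),
    cox = .coxWork(ydata$time, ydata$event, eta))
}

# gradient of (1/n) * unscaled NLL with respect to the columns of X
.gradNLL <- function(family, X, ydata, eta) {
  n <- nrow(X)
  switch(family,
    logistic = drop(crossprod(X, .expit(eta) - ydata$y)) / n,
    gaussian = drop(crossprod(X, eta - ydata$y)) / n,
    cox = -drop(crossprod(X, .coxWork(ydata$time, ydata$event, eta)$u)) / n)
}

#' Negative log-(partial-)likelihood
#'
#' The unscaled negative log-likelihood (logistic: binomial; gaussian: half
#' residual sum of squares) or negative Breslow-ties log partial likelihood
#' (Cox) at the given coefficients. The penalized objective used by
#' [penalizedFit()] is this quantity divided by the number of samples, plus
#' the penalty term.
#'
#' @param data a [MolecularDataSet-class].
#' @param coefficients coefficient vector (length = number of features, in
#'   feature order; a named vector is matched by name).
#' @param intercept intercept (logistic/gaussian only).
#' @param includeClinical include the dataset's clinical covariates (their
#'   coefficients must then be appended to `coefficients`).
#' @return a single number.
#' @export
negLogLik <- function(data, coefficients, intercept = 0,
                      includeClinical = FALSE) {
  stopifnot(is(data, "MolecularDataSet"))
  X <- .designMatrix(data, includeClinical)
  if (!all(is.finite(X))) .err("penomics_domain", "non-finite covariates")
  if (!is.null(names(coefficients)))
    coefficients <- coefficients[colnames(X)]
  stopifnot(length(coefficients) == ncol(X))
  eta <- drop(X %*% coefficients)
  family <- .familyOf(data)
  ydata <- .ydataOf(data)
  if (family == "logistic") eta <- eta + intercept
  .workingResponse(family, ydata, eta)$nll
}

.familyOf <- function(data) {
  if (identical(outcomeType(data), "binary")) "logistic" else "cox"
}

.ydataOf <- function(data) {
  cd <- SummarizedExperiment::colData(data)
  if (identical(outcomeType(data), "binary")) list(y = as.numeric(cd$status))
  else list(time = as.numeric(cd$time), event = as.numeric(cd$event))
}

.designMatrix <- function(data, includeClinical = FALSE) {
  X <- covariates(data)
  if (includeClinical) {
    cl <- clinicalMatrix(data)
    if (!is.null(cl)) X <- cbind(X, cl)
  }
  X
}

## ---- standardization --------------------------------------------------

# Standardize columns to mean 0 (intercept families) and population sd 1.
# Zero-variance columns keep scale 1. `which` marks columns to standardize.
.standardize <- function(X, which, center) {
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (any(which)) {
    sub <- X[, which, drop = FALSE]
    mu <- colMeans(sub)
    if (center) ctr[which] <- mu
    sd_n <- sqrt(colMeans(sweep(sub, 2, mu, "-")^2))
    sd_n[sd_n <= 0] <- 1
    scl[which] <- sd_n
  }
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}

## ---- core solver ------------------------------------------------------

# IRLS + cyclic coordinate descent on an already-standardized design.
.fitCore <- function(X, family, ydata, lambda, pf, ridge,
                     tol = 1e-7, maxSweeps = 1e5,
                     betaInit = NULL, b0Init = NULL) {
  n <- nrow(X); p <- ncol(X)
  fitIntercept <- family %in% c("logistic", "gaussian")
  beta <- betaInit %||% numeric(p)
  b0 <- b0Init %||% switch(family,
    logistic = .logit(min(max(mean(ydata$y), 1e-6), 1 - 1e-6)),
    gaussian = mean(ydata$y),
    cox = 0)
  maxOuter <- if (identical(family, "gaussian")) 1L else 100L
  conv <- FALSE
  budget <- maxSweeps          # total coordinate-sweep budget for this fit
  for (it in seq_len(maxOuter)) {
    eta <- drop(X %*% beta) + if (fitIntercept) b0 else 0
    wz <- .workingResponse(family, ydata, eta)
    res <- .cd_wls(X, wz$w, wz$z, beta, b0, fitIntercept,
                   lambda, pf, ridge, tol * 1e-2, as.integer(budget))
    budget <- budget - res$sweeps
    delta <- max(abs(res$beta - beta),
                 if (fitIntercept) abs(res$intercept - b0) else 0)
    beta <- res$beta; b0 <- res$intercept
    if (identical(family, "gaussian") ||
        delta < tol * max(1, max(abs(beta)))) {
      conv <- res$converged
      break
    }
    if (budget <= 0) break     # sweep budget exhausted: flagged unconverged
  }
  eta <- drop(X %*% beta) + if (fitIntercept) b0 else 0
  nll <- .workingResponse(family, ydata, eta)$nll
  fin <- is.finite(pf)
  penTerm <- if (ridge) sum(pf[fin] * beta[fin]^2) else sum(pf[fin] * abs(beta[fin]))
  list(beta = beta, intercept = if (fitIntercept) b0 else 0,
       converged = conv, objective = nll / n + lambda * penTerm, nll = nll)
}

## ---- lambda path ------------------------------------------------------

#' Regularization path of penalty values
#'
#' Computes `lambda_max` -- the smallest penalty at which the l1 solution is
#' entirely zero, obtained from the gradient of the unpenalized loss at the
#' null model (`max_j |grad_j| / pf_j`) -- and returns a strictly decreasing
#' log-spaced grid down to `lambda_max * lambdaMinRatio`. For the ridge
#' penalty, which never zeroes coefficients exactly, the same grid is scaled
#' up by 100 so that its largest value shrinks comparably hard.
#'
#' @param data a [MolecularDataSet-class].
#' @param penalty penalty family.
#' @param weights adaptive weights (adaptive lasso only).
#' @param excluded feature IDs carrying infinite penalty.
#' @param nLambda number of grid points (default 100).
#' @param lambdaMinRatio smallest/largest ratio; default 1e-2 when the
#'   feature count exceeds the sample count, else 1e-3.
#' @param standardize standardize continuous covariates internally (default:
#'   TRUE for Z-score matrices, FALSE for binary indicator matrices).
#' @param includeClinical include clinical covariates unpenalized.
#' @return decreasing numeric vector of penalty values; `values[1]` is
#'   `lambda_max` (on the internal `(1/n) loss` scale).
#' @export
lambdaPath <- function(data, penalty = "lasso", weights = NULL,
                       excluded = character(), nLambda = 100,
                       lambdaMinRatio = NULL, standardize = NULL,
                       includeClinical = FALSE) {
  prep <- .prepareProblem(data, penalty, weights, excluded,
                          standardize, includeClinical)
  .lambdaGrid(prep, nLambda, lambdaMinRatio,
              ridge = identical(penalty, "ridge"))
}

.lambdaGrid <- function(prep, nLambda = 100, lambdaMinRatio = NULL,
                        ridge = FALSE) {
  X <- prep$X; ydata <- prep$ydata; family <- prep$family; pf <- prep$pf
  n <- nrow(X); p <- ncol(X)
  eta0 <- if (identical(family, "logistic"))
    rep(.logit(min(max(mean(ydata$y), 1e-6), 1 - 1e-6)), n)
  else if (identical(family, "gaussian")) rep(mean(ydata$y), n)
  else rep(0, n)
  g <- abs(.gradNLL(family, X, ydata, eta0))
  ok <- is.finite(pf) & pf > 0
  if (!any(ok) || all(g[ok] == 0))
    .err("penomics_degenerate",
         "cannot build a lambda path: no penalized feature with signal "
         %+% "(all-zero covariates?)")
  # nudge above the exact boundary so the first grid point is strictly null
  lmax <- max(g[ok] / pf[ok]) * (1 + 1e-6)
  if (ridge) lmax <- lmax * 100
  ratio <- lambdaMinRatio %||% if (p > n) 1e-2 else 1e-3
  exp(seq(log(lmax), log(lmax * ratio), length.out = nLambda))
}

`%+%` <- function(a, b) paste0(a, b)

## ---- shared problem preparation ---------------------------------------

# Assemble the internal optimization problem: standardized design, y-data,
# penalty factors (clinical columns unpenalized; excluded features Inf).
.prepareProblem <- function(data, penalty, weights, excluded,
                            standardize, includeClinical) {
  stopifnot(is(data, "MolecularDataSet"))
  penalty <- match.arg(penalty, .PENALTIES)
  family <- .familyOf(data)
  ydata <- .ydataOf(data)
  Xmol <- covariates(data)
  feats <- colnames(Xmol)
  cl <- if (includeClinical) clinicalMatrix(data) else NULL
  X <- if (is.null(cl)) Xmol else cbind(Xmol, cl)
  if (!all(is.finite(X))) .err("penomics_domain", "non-finite covariates")
  if (identical(family, "logistic") && length(unique(ydata$y)) < 2L)
    .err("penomics_degenerate", "single-class binary outcome")
  if (identical(family, "cox") && !any(ydata$event == 1))
    .err("penomics_degenerate", "survival outcome with no events")
  if (is.null(standardize)) standardize <- identical(featureKind(data), "zscore")
  whichStd <- logical(ncol(X))
  whichStd[seq_along(feats)] <- standardize
  if (!is.null(cl)) whichStd[(length(feats) + 1):ncol(X)] <- TRUE
  std <- .standardize(X, whichStd,
                      center = family %in% c("logistic", "gaussian"))
  pf <- rep(1, ncol(X))
  names(pf) <- colnames(X)
  if (identical(penalty, "adaptive_lasso")) {
    if (is.null(weights) || !length(weights))
      .err("penomics_domain", "adaptive lasso requires first-stage weights")
    if (any(weights <= 0)) .err("penomics_domain", "adaptive weights must be > 0")
    pf[] <- Inf                      # features without a weight are excluded
    pf[names(weights)] <- 1 / weights
  }
  pf[excluded] <- Inf
  if (!is.null(cl)) pf[colnames(cl)] <- 0   # clinical: always unpenalized
  list(X = std$X, center = std$center, scale = std$scale, pf = pf,
       family = family, ydata = ydata, penalty = penalty,
       features = feats, clinical = colnames(cl) %||% character())
}

.finishFit <- function(prep, core, lambda) {
  betaStd <- core$beta
  betaOrig <- betaStd / prep$scale
  b0 <- core$intercept - sum(betaStd * prep$center / prep$scale)
  names(betaOrig) <- names(prep$pf)
  new("PenalizedFit",
      family = prep$family, penalty = prep$penalty,
      intercept = if (prep$family %in% c("logistic", "gaussian")) b0 else 0,
      coefficients = betaOrig, lambda = lambda,
      objective = core$objective, converged = core$converged,
      std = list(center = prep$center, scale = prep$scale,
                 clinical = prep$clinical),
      penaltyFactors = prep$pf, nObs = nrow(prep$X))
}

## ---- path fitting with warm starts ------------------------------------

# Warm-started fits along a decreasing lambda grid. As in other pathwise
# solvers, the path stops early once the model is essentially saturated --
# fraction of null deviance explained above `devMax`, or a relative
# deviance improvement below `devTol` between neighbours -- which also
# guards against the quasi-separated regime where coefficients diverge;
# later grid points reuse the last solution. `nFitted` reports how many
# grid points were fitted fresh.
# Path/CV fits use a looser convergence tolerance than the final fit: the
# CV criterion is insensitive at 1e-5, and the IRLS outer loop for Cox
# contracts only linearly under the diagonal-Hessian approximation.
.pathFit <- function(prep, lambdas, ridge, tol = 1e-5, maxSweeps = 2e4,
                     devMax = 0.999, devTol = 1e-5, betaMax = 5) {
  p <- ncol(prep$X)
  nl <- length(lambdas)
  betas <- matrix(0, p, nl)
  b0s <- numeric(nl)
  convs <- logical(nl)
  beta <- numeric(p); b0 <- NULL
  nullNll <- NA_real_; prevNll <- NA_real_
  nFitted <- nl
  for (k in seq_len(nl)) {
    core <- .fitCore(prep$X, prep$family, prep$ydata, lambdas[k], prep$pf,
                     ridge, tol, maxSweeps, betaInit = beta, b0Init = b0)
    beta <- core$beta; b0 <- core$intercept
    betas[, k] <- beta; b0s[k] <- b0; convs[k] <- core$converged
    if (k == 1L) nullNll <- core$nll
    stop_ <- FALSE
    if (nullNll > 0) {
      r <- 1 - core$nll / nullNll
      if (r > devMax) stop_ <- TRUE
      if (k > 1L && is.finite(prevNll) &&
          (prevNll - core$nll) / nullNll < devTol * max(r, 0)) stop_ <- TRUE
      # divergence guard: entering the quasi-separated regime, or solver
      # sweep budget exhausted -- deeper lambdas are not meaningful
      if (max(abs(beta)) > betaMax || !core$converged) stop_ <- TRUE
    }
    prevNll <- core$nll
    if (stop_ && k < nl) {
      for (k2 in (k + 1L):nl) {
        betas[, k2] <- beta; b0s[k2] <- b0; convs[k2] <- core$converged
      }
      nFitted <- k
      break
    }
  }
  list(betas = betas, intercepts = b0s, converged = convs,
       nFitted = nFitted)
}

## ---- cross-validated tuning -------------------------------------------

#' Cross-validated selection of the penalty level
#'
#' Selects lambda by K-fold cross-validation over the regularization path:
#' mean held-out binomial deviance for the logistic family, and the
#' Verweij-van Houwelingen cross-validated partial-likelihood deviance for
#' the Cox family. Folds are stratified by outcome class (logistic) or event
#' indicator (Cox) and fully determined by `seed`. Among penalty values
#' tying at the minimal criterion the largest (most parsimonious) is chosen.
#'
#' @inheritParams lambdaPath
#' @param nFolds number of tuning folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param lambdas optional explicit decreasing path; default [lambdaPath()].
#' @return list with `lambdaOpt`, `lambdas`, `cvCurve` (criterion per
#'   lambda), `seed`, `nFolds`.
#' @export
cvTune <- function(data, penalty = "lasso", weights = NULL,
                   excluded = character(), nFolds = 10, seed = 1,
                   lambdas = NULL, standardize = NULL,
                   includeClinical = FALSE) {
  if (nFolds < 2) .err("penomics_domain", "'nFolds' must be >= 2")
  prep <- .prepareProblem(data, penalty, weights, excluded,
                          standardize, includeClinical)
  ridge <- identical(penalty, "ridge")
  if (is.null(lambdas)) lambdas <- .lambdaGrid(prep, ridge = ridge)
  .cvTuneCore(prep, lambdas, ridge, nFolds, seed)
}

.cvTuneCore <- function(prep, lambdas, ridge, nFolds, seed) {
  family <- prep$family; ydata <- prep$ydata
  n <- nrow(prep$X)
  # truncate the grid where the full-data path saturates
  full <- .pathFit(prep, lambdas, ridge)
  lambdas <- lambdas[seq_len(full$nFitted)]
  strata <- if (identical(family, "cox")) ydata$event
            else if (identical(family, "logistic")) ydata$y
            else rep(1, n)
  if (identical(family, "cox") && sum(ydata$event == 1) < nFolds)
    .err("penomics_fold", "fewer events (%d) than folds (%d)",
         sum(ydata$event == 1), nFolds)
  folds <- .makeFolds(strata, nFolds, seed)
  if (identical(family, "logistic")) {
    bad <- vapply(seq_len(nFolds), function(k)
      length(unique(ydata$y[folds != k])) < 2L, logical(1))
    if (any(bad))
      .err("penomics_fold", "fold %d leaves a single-class training set",
           which(bad)[1])
  }
  crit <- matrix(NA_real_, nFolds, length(lambdas))
  for (k in seq_len(nFolds)) {
    tr <- folds != k
    prepTr <- prep
    prepTr$X <- prep$X[tr, , drop = FALSE]
    prepTr$ydata <- lapply(ydata, `[`, tr)
    pfit <- .pathFit(prepTr, lambdas, ridge)
    for (l in seq_along(lambdas)) {
      beta <- pfit$betas[, l]
      if (identical(family, "logistic")) {
        etaTe <- drop(prep$X[!tr, , drop = FALSE] %*% beta) +
          pfit$intercepts[l]
        pTe <- pmin(pmax(.expit(etaTe), 1e-10), 1 - 1e-10)
        yTe <- ydata$y[!tr]
        crit[k, l] <- mean(-2 * (yTe * log(pTe) + (1 - yTe) * log(1 - pTe)))
      } else if (identical(family, "cox")) {
        etaAll <- drop(prep$X %*% beta)
        plFull <- .coxPL(ydata$time, ydata$event, etaAll)
        plTr <- .coxPL(ydata$time[tr], ydata$event[tr], etaAll[tr])
        crit[k, l] <- -2 * (plFull - plTr)
      } else {
        etaTe <- drop(prep$X[!tr, , drop = FALSE] %*% beta) +
          pfit$intercepts[l]
        crit[k, l] <- mean((ydata$y[!tr] - etaTe)^2)
      }
    }
  }
  curve <- colMeans(crit)
  best <- min(curve)
  lambdaOpt <- lambdas[which(curve <= best + 1e-10 * (1 + abs(best)))[1]]
  list(lambdaOpt = lambdaOpt, lambdas = lambdas, cvCurve = curve,
       seed = seed, nFolds = nFolds)
}

## ---- top-level fit ----------------------------------------------------

#' Fit a penalized logistic or Cox regression
#'
#' Minimizes `(1/n) * negative log-(partial-)likelihood + lambda * penalty`
#' by iteratively reweighted least squares with cyclic coordinate descent
#' (soft-thresholding for the l1 penalties). The intercept (logistic) is
#' never penalized; coefficients are returned on the original covariate
#' scale. With `lambda = "cv"` the penalty level is chosen by [cvTune()].
#'
#' Continuous (Z-score) covariates are standardized to unit variance
#' internally and back-transformed; binary 0/1 covariates are left on their
#' own scale by default so that alteration-indicator coefficients stay
#' interpretable (`standardize` overrides). A penalty stated for the
#' unscaled log-likelihood objective relates to the internal one by
#' `lambda_unscaled = n * lambda`.
#'
#' @param data a [MolecularDataSet-class].
#' @param penalty `"ridge"`, `"lasso"` or `"adaptive_lasso"`.
#' @param lambda positive penalty level on the internal `(1/n) loss` scale,
#'   or `"cv"`.
#' @param weights named positive adaptive weights `w_j` (adaptive lasso
#'   only): the applied penalty factor is `1 / w_j`, and active-set features
#'   of the first stage without a weight are excluded. Usually produced by
#'   [adaptiveWeights()].
#' @param excluded feature IDs forced to coefficient 0 (infinite penalty).
#' @param standardize logical or NULL (kind-dependent default, see Details).
#' @param includeClinical include the dataset's clinical covariates as
#'   unpenalized columns.
#' @param nFoldsTune,seed tuning-CV controls (used when `lambda = "cv"`).
#' @param tol relative coefficient-change convergence tolerance.
#' @param maxSweeps maximum coordinate sweeps per weighted least-squares
#'   solve.
#' @return a [PenalizedFit-class].
#' @export
penalizedFit <- function(data, penalty = c("lasso", "ridge", "adaptive_lasso"),
                         lambda = "cv", weights = NULL,
                         excluded = character(), standardize = NULL,
                         includeClinical = FALSE, nFoldsTune = 10, seed = 1,
                         tol = 1e-7, maxSweeps = 1e5) {
  penalty <- match.arg(penalty)
  if (is(weights, "PenaltySpec")) {
    spec <- weights
    penalty <- spec@penalty
    excluded <- union(excluded, spec@excluded)
    weights <- if (length(spec@weights)) spec@weights else NULL
    if (identical(lambda, "cv") && !is.na(spec@lambda)) lambda <- spec@lambda
  }
  prep <- .prepareProblem(data, penalty, weights, excluded,
                          standardize, includeClinical)
  ridge <- identical(penalty, "ridge")
  tuned <- NULL
  if (identical(lambda, "cv") || (is.numeric(lambda) && is.na(lambda))) {
    lambdas <- .lambdaGrid(prep, ridge = ridge)
    tuned <- .cvTuneCore(prep, lambdas, ridge, nFoldsTune, seed)
    lambda <- tuned$lambdaOpt
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
      (!ridge && lambda <= 0))
    .err("penomics_domain", "'lambda' must be positive (>= 0 for ridge)")
  # warm-start down a short path for stability at small lambda
  lmax <- tryCatch(.lambdaGrid(prep, nLambda = 2, ridge = ridge)[1],
                   error = function(e) NA_real_)
  beta <- numeric(ncol(prep$X)); b0 <- NULL
  if (is.finite(lmax) && lambda < lmax) {
    warm <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-6)),
                    length.out = 15))[-15]
    warm <- warm[warm > lambda]
    if (length(warm)) {
      wf <- .pathFit(prep, warm, ridge, tol, maxSweeps)
      beta <- wf$betas[, length(warm)]
      b0 <- wf$intercepts[length(warm)]
    }
  }
  core <- .fitCore(prep$X, prep$family, prep$ydata, lambda, prep$pf, ridge,
                   tol, maxSweeps, betaInit = beta, b0Init = b0)
  if (!core$converged)
    warning("penalized fit did not converge; result flagged")
  fit <- .finishFit(prep, core, lambda)
  if (!is.null(tuned)) fit@std$tuning <- tuned
  fit
}

#' Adaptive-lasso weights from a first-stage lasso fit
#'
#' The adaptive weight of feature j is `w_j = |beta_hat_j^lasso|` for
#' features active in the first stage; features with a zero first-stage
#' coefficient receive an infinite penalty (they are excluded and stay at
#' zero), so the adaptive-lasso active set is always a subset of the lasso
#' active set.
#'
#' @param firstStage a lasso [PenalizedFit-class].
#' @return a [PenaltySpec-class] with `penalty = "adaptive_lasso"`.
#' @export
adaptiveWeights <- function(firstStage) {
  stopifnot(is(firstStage, "PenalizedFit"))
  if (!identical(firstStage@penalty, "lasso"))
    .err("penomics_domain", "adaptive weights require a first-stage lasso fit")
  co <- firstStage@coefficients
  co <- co[setdiff(names(co), firstStage@std$clinical)]
  act <- co[co != 0]
  if (!length(act))
    .err("penomics_nothing_to_refit",
         "empty first-stage active set: nothing to refit")
  new("PenaltySpec", penalty = "adaptive_lasso", lambda = NA_real_,
      weights = abs(act), excluded = names(co)[co == 0])
}

#' Karush-Kuhn-Tucker certification of a penalized fit
#'
#' Recomputes the gradient of the `(1/n)`-scaled loss at the returned
#' solution (on the internal standardized scale) and measures the worst
#' violation of the first-order optimality conditions: for the l1 penalties,
#' inactive coordinates must satisfy `|grad_j| <= lambda * pf_j` and active
#' coordinates `grad_j = -lambda * pf_j * sign(beta_j)`; for ridge,
#' `grad_j + 2 * lambda * pf_j * beta_j = 0`.
#'
#' @param fit a [PenalizedFit-class].
#' @param data the [MolecularDataSet-class] it was fitted on.
#' @param tol violation tolerance (default 1e-6).
#' @return list with `ok` (logical), `maxViolation`, and the per-coordinate
#'   `violations` vector.
#' @export
kktCheck <- function(fit, data, tol = 1e-6) {
  stopifnot(is(fit, "PenalizedFit"))
  includeClinical <- length(fit@std$clinical) > 0
  X <- .designMatrix(data, includeClinical)
  X <- X[, names(fit@coefficients), drop = FALSE]
  Xs <- sweep(sweep(X, 2, fit@std$center, "-"), 2, fit@std$scale, "/")
  betaStd <- fit@coefficients * fit@std$scale
  family <- fit@family
  ydata <- .ydataOf(data)
  eta <- drop(X %*% fit@coefficients) +
    if (family %in% c("logistic", "gaussian")) fit@intercept else 0
  g <- .gradNLL(family, Xs, ydata, eta)
  pf <- fit@penaltyFactors
  lam <- fit@lambda
  viol <- numeric(length(g))
  fin <- is.finite(pf)
  if (identical(fit@penalty, "ridge")) {
    viol[fin] <- abs(g[fin] + 2 * lam * pf[fin] * betaStd[fin])
  } else {
    act <- fin & betaStd != 0
    inact <- fin & betaStd == 0
    viol[act] <- abs(g[act] + lam * pf[act] * sign(betaStd[act]))
    viol[inact] <- pmax(abs(g[inact]) - lam * pf[inact], 0)
  }
  names(viol) <- names(fit@coefficients)
  list(ok = max(viol) <= tol, maxViolation = max(viol), violations = viol)
}
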