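## Post-selection ("selective") inference for lasso-type fits via
## polyhedral conditioning: the event {active set E, signs s} of a lasso
## solution is an affine set {A y <= b} in the (working) response, so the
## law of any linear statistic eta'y conditional on selection is a
## truncated Gaussian, yielding exact pivots on the working model.

# Truncated-normal CDF and survival P(Z <= x | a <= Z <= b) and its
# complement, Z ~ N(mean, sd^2), each computed in whichever Gaussian tail
# keeps the arithmetic free of cancellation.
.truncnormTails <- function(x, mean, sd, a, b) {
  za <- (a - mean) / sd; zb <- (b - mean) / sd; zx <- (x - mean) / sd
  zx <- min(max(zx, za), zb)
  Q <- function(z) pnorm(z, lower.tail = FALSE)
  if (za > 0) {
    # whole interval in the right tail: survival functions only
    den <- Q(za) - Q(zb)
    if (den <= 0) return(c(NA_real_, NA_real_))
    c((Q(za) - Q(zx)) / den, (Q(zx) - Q(zb)) / den)
  } else if (zb < 0) {
    den <- pnorm(zb) - pnorm(za)
    if (den <= 0) return(c(NA_real_, NA_real_))
    c((pnorm(zx) - pnorm(za)) / den, (pnorm(zb) - pnorm(zx)) / den)
  } else {
    den <- pnorm(zb) - pnorm(za)
    if (den <= 0) return(c(NA_real_, NA_real_))
    c((pnorm(zx) - pnorm(za)) / den, (Q(zx) - Q(zb)) / den)
  }
}

.truncnormCDF <- function(x, mean, sd, a, b) .truncnormTails(x, mean, sd, a, b)[1]

# Two-sided truncated-Gaussian pivot for observed statistic v with null
# mean 0, scale sd, truncated to [vlo, vhi].
.truncnormPivot <- function(v, sd, vlo, vhi) {
  t <- .truncnormTails(v, 0, sd, vlo, vhi)
  if (anyNA(t)) return(NA_real_)
  min(2 * min(t), 1)
}

# Truncation interval of eta'y implied by {A y <= b} (polyhedral lemma,
# isotropic covariance): decompose y = z + c * (eta'y) with c = eta/||eta||^2.
.truncationInterval <- function(A, b, eta, y) {
  ee <- sum(eta^2)
  c_ <- eta / ee
  v <- sum(eta * y)
  z <- y - c_ * v
  rho <- drop(A %*% c_)
  resid <- b - drop(A %*% z)
  tolr <- 1e-10 * max(1, max(abs(b)))
  vlo <- -Inf; vhi <- Inf
  neg <- rho < -1e-12; pos <- rho > 1e-12
  if (any(neg)) vlo <- max(resid[neg] / rho[neg])
  if (any(pos)) vhi <- min(resid[pos] / rho[pos])
  # numerical slack: the observed statistic must lie inside
  if (v < vlo && v > vlo - tolr) vlo <- v
  if (v > vhi && v < vhi + tolr) vhi <- v
  list(vlo = vlo, vhi = vhi, v = v)
}

# Lee et al. affine selection constraints for a standard lasso
#   min 1/2 ||y - X b||^2 + Lambda ||b||_1
# with active index set E (columns of X), sign vector s.
.lassoConstraints <- function(X, E, s, Lambda) {
  XE <- X[, E, drop = FALSE]
  G <- crossprod(XE)
  Gi <- tryCatch(solve(G), error = function(e)
    .err("penomics_degenerate", "singular active-set Gram matrix"))
  XEp <- Gi %*% t(XE)                       # (X_E^T X_E)^{-1} X_E^T
  A1 <- -diag(s, nrow = length(s)) %*% XEp
  b1 <- -Lambda * drop(diag(s, nrow = length(s)) %*% Gi %*% s)
  notE <- setdiff(seq_len(ncol(X)), E)
  if (length(notE)) {
    Xm <- X[, notE, drop = FALSE]
    P <- XE %*% XEp                         # projection onto col(X_E)
    M <- t(Xm) %*% (diag(nrow(X)) - P) / Lambda
    off <- drop(t(Xm) %*% t(XEp) %*% s)
    A2 <- M;  b2 <- 1 - off
    A3 <- -M; b3 <- 1 + off
    A <- rbind(A1, A2, A3); b <- c(b1, b2, b3)
  } else {
    A <- A1; b <- b1
  }
  list(A = A, b = b, XEp = XEp)
}

# Shared inference core on a working Gaussian problem (y, X): statistic for
# feature j in E is the E-restricted least-squares coordinate e_j' X_E^+ y.
.selInfCore <- function(X, y, E, s, Lambda, sigma) {
  cons <- .lassoConstraints(X, E, s, Lambda)
  k <- length(E)
  out <- data.frame(idx = E, pValue = NA_real_,
                    Vminus = NA_real_, Vplus = NA_real_)
  for (i in seq_len(k)) {
    eta <- cons$XEp[i, ]                    # row i of X_E^+ = eta_j' y
    ti <- .truncationInterval(cons$A, cons$b, eta, y)
    sdj <- sigma * sqrt(sum(eta^2))
    if (is.finite(ti$vhi) && is.finite(ti$vlo) &&
        ti$vhi - ti$vlo < 1e-10 * max(1, sdj)) {
      next                                   # degenerate truncation: flagged
    }
    out$pValue[i] <- .truncnormPivot(ti$v, sdj, ti$vlo, ti$vhi)
    out$Vminus[i] <- ti$vlo
    out$Vplus[i] <- ti$vhi
  }
  out
}

#' Post-selection p-values for a lasso-type fit
#'
#' Computes "correct" p-values for the features selected by a lasso or
#' adaptive-lasso fit at a fixed penalty level, conditioning on the
#' selection event. For the logistic and Cox families the fit is first
#' linearized: the working response and weights of the IRLS step at the
#' solution define a weighted least-squares lasso whose solution is the fit
#' itself, and the selection event \{active set, signs\} is encoded as affine
#' constraints on the working response. Adaptive penalty factors are
#' absorbed by rescaling the working design columns so the event is again a
#' standard lasso event. Each selected feature's two-sided truncated-
#' Gaussian pivot is reported together with its truncation interval.
#'
#' Inference is performed at the penalty level actually used -- typically
#' the CV-chosen one -- although the conditioning formally assumes a fixed
#' lambda; this is the usual approximation for this workflow. The noise
#' scale of the working Gaussian problem is fixed at 1 (the GLM working-
#' model convention).
#'
#' @param fit a lasso or adaptive-lasso [PenalizedFit-class] with non-empty
#'   active set.
#' @param data the [MolecularDataSet-class] the fit was computed on.
#' @param sigma plug-in noise scale (default 1 for the logistic/Cox working
#'   problems).
#' @return a [SelectiveInferenceResult-class]; features with numerically
#'   degenerate truncation carry `NA` p-values.
#' @export
selectivePvalues <- function(fit, data, sigma = NULL) {
  stopifnot(is(fit, "PenalizedFit"), is(data, "MolecularDataSet"))
  if (!fit@penalty %in% c("lasso", "adaptive_lasso"))
    .err("penomics_domain", "selective inference needs an l1-penalized fit")
  pf <- fit@penaltyFactors
  betaStd <- fit@coefficients * fit@std$scale
  penal <- is.finite(pf) & pf > 0
  act <- penal & betaStd != 0
  if (!any(act)) .err("penomics_empty_active",
                      "empty active set: no features to test")
  includeClinical <- length(fit@std$clinical) > 0
  X <- .designMatrix(data, includeClinical)
  X <- X[, names(fit@coefficients), drop = FALSE]
  Xs <- sweep(sweep(X, 2, fit@std$center, "-"), 2, fit@std$scale, "/")
  family <- fit@family
  ydata <- .ydataOf(data)
  eta <- drop(X %*% fit@coefficients) +
    if (family %in% c("logistic", "gaussian")) fit@intercept else 0
  wz <- .workingResponse(family, ydata, eta)
  sw <- sqrt(wz$w)
  ytil <- sw * wz$z
  Xtil <- Xs * sw
  # project out the (unpenalized) intercept and clinical columns
  U <- NULL
  if (family %in% c("logistic", "gaussian")) U <- cbind(U, sw)
  unpen <- which(pf == 0)
  if (length(unpen)) U <- cbind(U, Xtil[, unpen, drop = FALSE])
  if (!is.null(U)) {
    Q <- qr.Q(qr(U))
    ytil <- ytil - Q %*% crossprod(Q, ytil)
    Xtil <- Xtil - Q %*% crossprod(Q, Xtil)
    ytil <- drop(ytil)
  }
  # absorb penalty factors: columns scaled by 1/pf make the penalty uniform
  keep <- which(penal)
  Xchk <- sweep(Xtil[, keep, drop = FALSE], 2, pf[keep], "/")
  Lambda <- fit@lambda * nrow(X)
  E <- match(which(act), keep)
  s <- sign(betaStd[act])
  if (is.null(sigma)) sigma <- 1
  core <- .selInfCore(Xchk, ytil, E, s, Lambda, sigma)
  ids <- names(fit@coefficients)[keep][core$idx]
  tab <- data.frame(featureID = ids,
                    coefficient = fit@coefficients[ids],
                    pValue = core$pValue,
                    Vminus = core$Vminus, Vplus = core$Vplus,
                    row.names = NULL)
  new("SelectiveInferenceResult", table = tab, lambda = fit@lambda,
      sigma = sigma, family = family)
}

#' Selective inference for a plain Gaussian lasso
#'
#' Direct interface for the Gaussian case (also the package's debugging /
#' calibration family): fits the lasso
#' `min (1/2n)||y - X b||^2 + lambda ||b||_1` (no intercept) and returns
#' selective p-values for the active features. When `sigma` is not given it
#' is estimated from the full least-squares residuals when `n > p`, else
#' fixed at 1.
#'
#' @param X numeric design matrix.
#' @param y numeric response.
#' @param lambda penalty level on the `(1/n)` loss scale.
#' @param sigma optional noise scale.
#' @return a [SelectiveInferenceResult-class].
#' @export
selectiveInferenceGaussian <- function(X, y, lambda, sigma = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(p))
  pfv <- rep(1, p)
  res <- .cd_wls(X, rep(1, n), y, numeric(p), 0, FALSE, lambda, pfv,
                 FALSE, 1e-12, 100000L)
  beta <- res$beta
  act <- which(beta != 0)
  if (!length(act)) .err("penomics_empty_active",
                         "empty active set: no features to test")
  if (is.null(sigma)) {
    sigma <- if (n > p + 1) {
      r <- qr.resid(qr(X), y)
      sqrt(sum(r^2) / (n - p))
    } else 1
  }
  core <- .selInfCore(X, y, act, sign(beta[act]), lambda * n, sigma)
  tab <- data.frame(featureID = colnames(X)[act],
                    coefficient = beta[act],
                    pValue = core$pValue,
                    Vminus = core$Vminus, Vplus = core$Vplus,
                    row.names = NULL)
  new("SelectiveInferenceResult", table = tab, lambda = lambda,
      sigma = sigma, family = "gaussian")
}
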