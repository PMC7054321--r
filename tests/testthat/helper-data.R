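# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# samples x features matrix with dimnames
mkMatrix <- function(values, nr, nc, kind = "zscore") {
  m <- matrix(values, nr, nc,
              dimnames = list(sprintf("S%02d", seq_len(nr)),
                              sprintf("g%02d", seq_len(nc))))
  molecularMatrix(m, kind)
}

# tiny aligned binary-outcome dataset from explicit pieces
mkBinaryDS <- function(X, y, kind = "zscore") {
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%02d", seq_len(ncol(X)))
  alignDataset(molecularMatrix(X, kind), binaryOutcome(rownames(X), y))
}

mkSurvivalDS <- function(X, time, event, kind = "zscore") {
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%02d", seq_len(ncol(X)))
  alignDataset(molecularMatrix(X, kind),
               survivalOutcome(rownames(X), time, event))
}

# write a small delimited matrix file; rows = list of character vectors
writeLinesTmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# independent step-up oracle for Benjamini-Hochberg selection
bhStepUpOracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  sel <- logical(m)
  if (length(k)) sel[p <= ps[max(k)]] <- TRUE
  sel
}

# explicit risk-set-sum Breslow log partial likelihood (quadratic-time)
coxPLOracle <- function(time, event, eta) {
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      atRisk <- time >= time[i]
      ll <- ll + eta[i] - log(sum(exp(eta[atRisk])))
    }
  }
  ll
}

# brute-force minimization of the written penalized objective for p <= 2:
# profile the intercept (1-D optimize) on a coefficient grid around `center`
bruteForceObjective <- function(ds, penalty, lambda, center,
                                width = 0.5, nGrid = 101) {
  X <- covariates(ds)
  family <- if (outcomeType(ds) == "binary") "logistic" else "cox"
  cd <- SummarizedExperiment::colData(ds)
  pen <- function(b) if (penalty == "ridge") sum(b^2) else sum(abs(b))
  objAt <- function(b) {
    if (family == "logistic") {
      y <- cd$status
      f <- function(b0) {
        eta <- b0 + drop(X %*% b)
        mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
      }
      opt <- stats::optimize(f, c(-20, 20), tol = 1e-10)
      opt$objective + lambda * pen(b)
    } else {
      eta <- drop(X %*% b)
      -coxPLOracle(cd$time, cd$event, eta) / nrow(X) + lambda * pen(b)
    }
  }
  p <- ncol(X)
  grids <- lapply(seq_len(p), function(j)
    seq(center[j] - width, center[j] + width, length.out = nGrid))
  best <- Inf
  if (p == 1) {
    for (b1 in grids[[1]]) best <- min(best, objAt(b1))
  } else {
    for (b1 in grids[[1]]) for (b2 in grids[[2]])
      best <- min(best, objAt(c(b1, b2)))
  }
  best
}
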