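test_that("negative log-likelihood closed forms hold", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  ds <- mkBinaryDS(X, y)
  # all-zero coefficients, zero intercept: n * ln 2
  expect_equal(negLogLik(ds, c(0, 0), intercept = 0), 10 * log(2))
  # duplicating every sample doubles the value
  X2 <- rbind(X, X)
  rownames(X2) <- sprintf("S%02d", 1:20)
  ds2 <- mkBinaryDS(X2, c(y, y))
  b <- c(0.3, -0.2)
  expect_equal(negLogLik(ds2, b, 0.1), 2 * negLogLik(ds, b, 0.1))

  # Cox at alpha = 0 with 3 distinct event times, no censoring: ln 6
  dsc <- mkSurvivalDS(matrix(rnorm(3), 3, 1), time = c(1, 2, 3),
                      event = c(1, 1, 1))
  expect_equal(negLogLik(dsc, 0), log(6))
})

test_that("Breslow partial likelihood matches explicit risk-set summation", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    tm <- sample(rexp(n), n)                       # some ties via rounding
    if (rep %% 2 == 0) tm <- round(tm, 1)
    ev <- rbinom(n, 1, 0.7)
    ev[sample(n, 1)] <- 1L
    eta <- rnorm(n)
    expect_equal(penomics:::.coxPL(tm, ev, eta), coxPLOracle(tm, ev, eta),
                 tolerance = 1e-10)
  }
})

test_that("lasso at lambda >= lambda_max yields an empty active set", {
  set.seed(5)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, plogis(X[, 1]))
  ds <- mkBinaryDS(X, y)
  path <- lambdaPath(ds, "lasso")
  expect_true(all(diff(path) < 0))
  fit <- penalizedFit(ds, penalty = "lasso", lambda = path[1])
  expect_length(activeSet(fit), 0)
  fit2 <- penalizedFit(ds, penalty = "lasso", lambda = path[1] * 2)
  expect_length(activeSet(fit2), 0)
  # just below lambda_max something enters
  fit3 <- penalizedFit(ds, penalty = "lasso", lambda = path[10])
  expect_gt(length(activeSet(fit3)), 0)
})

test_that("p <= 2 fits match brute-force minimization of the written objective", {
  set.seed(9)
  # logistic, p = 1, ridge and lasso
  X1 <- matrix(rnorm(40), 40, 1)
  y1 <- rbinom(40, 1, plogis(1.2 * X1[, 1]))
  ds1 <- mkBinaryDS(X1, y1)
  for (pen in c("ridge", "lasso")) {
    f <- penalizedFit(ds1, penalty = pen, lambda = 0.1, standardize = FALSE)
    oracle <- bruteForceObjective(ds1, pen, 0.1, coef(f), width = 0.3,
                                  nGrid = 201)
    expect_lte(f@objective, oracle + 1e-4)
    expect_lt(abs(f@objective - oracle), 1e-4)
  }
  # logistic, p = 2
  X2 <- matrix(rnorm(100), 50, 2)
  y2 <- rbinom(50, 1, plogis(X2[, 1] - X2[, 2]))
  ds2 <- mkBinaryDS(X2, y2)
  f2 <- penalizedFit(ds2, penalty = "lasso", lambda = 0.05,
                     standardize = FALSE)
  oracle2 <- bruteForceObjective(ds2, "lasso", 0.05, coef(f2), width = 0.25,
                                 nGrid = 81)
  expect_lt(abs(f2@objective - oracle2), 1e-4)
  # Cox, p = 2, n = 20: objective no worse than any grid point around it
  set.seed(10)
  Xc <- matrix(rnorm(40), 20, 2)
  tm <- rexp(20, 0.2 * exp(0.8 * Xc[, 1]))
  ev <- rbinom(20, 1, 0.8); ev[1] <- 1L
  dsc <- mkSurvivalDS(Xc, tm, ev)
  fc <- penalizedFit(dsc, penalty = "lasso", lambda = 0.05,
                     standardize = FALSE)
  oraclec <- bruteForceObjective(dsc, "lasso", 0.05, coef(fc), width = 0.3,
                                 nGrid = 81)
  expect_lte(fc@objective, oraclec + 1e-4)
})

test_that("ridge at lambda = 0 equals the unpenalized MLE", {
  set.seed(12)
  X <- matrix(rnorm(120), 60, 2)
  y <- rbinom(60, 1, plogis(0.8 * X[, 1] - 0.5 * X[, 2]))
  ds <- mkBinaryDS(X, y)
  f <- penalizedFit(ds, penalty = "ridge", lambda = 0, standardize = FALSE)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(coef(f)), unname(coef(ref)[-1]), tolerance = 1e-4)
  expect_equal(f@intercept, unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("solutions agree with an independent pathwise solver", {
  skip_if_not_installed("glmnet")
  set.seed(21)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(X[, 1] - 0.7 * X[, 2]))
  ds <- mkBinaryDS(X, y)
  lam <- 0.04
  f <- penalizedFit(ds, penalty = "lasso", lambda = lam, standardize = FALSE)
  g <- glmnet::glmnet(X, y, family = "binomial", lambda = lam,
                      standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(coef(f)), as.numeric(g$beta), tolerance = 1e-6)
  expect_equal(f@intercept, as.numeric(g$a0), tolerance = 1e-6)
  # ridge: their penalty is lambda/2 * ||b||^2, ours lambda * ||b||^2
  fr <- penalizedFit(ds, penalty = "ridge", lambda = lam, standardize = FALSE)
  gr <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = 2 * lam, standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(coef(fr)), as.numeric(gr$beta), tolerance = 1e-5)
  # Cox
  tm <- rexp(n, 0.1 * exp(0.8 * X[, 1]))
  ev <- as.integer(tm < rexp(n, 0.05)); ev[1] <- 1L
  dsc <- mkSurvivalDS(X, tm, ev)
  fcx <- penalizedFit(dsc, penalty = "lasso", lambda = lam,
                      standardize = FALSE)
  gcx <- glmnet::glmnet(X, survival::Surv(tm, ev), family = "cox",
                        lambda = lam, standardize = FALSE, thresh = 1e-12)
  expect_equal(unname(coef(fcx)), as.numeric(gcx$beta), tolerance = 1e-5)
})

test_that("KKT conditions certify l1 solutions across datasets and lambdas", {
  set.seed(33)
  for (rep in 1:4) {
    n <- 60; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, plogis(X[, 1] - X[, 2]))
    ds <- mkBinaryDS(X, y)
    for (lam in c(0.02, 0.08)) {
      f <- penalizedFit(ds, penalty = "lasso", lambda = lam)
      expect_true(kktCheck(f, ds, tol = 1e-6)$ok)
    }
    tm <- rexp(n, 0.2 * exp(0.6 * X[, 1])); ev <- rbinom(n, 1, 0.75)
    ev[1] <- 1L
    dsc <- mkSurvivalDS(X, tm, ev)
    fc <- penalizedFit(dsc, penalty = "lasso", lambda = 0.04)
    expect_true(kktCheck(fc, dsc, tol = 1e-6)$ok)
  }
})

test_that("rescaling covariates rescales lambda_max and coefficients coherently", {
  set.seed(44)
  X <- matrix(rnorm(60), 60, 1)
  y <- rbinom(60, 1, plogis(X[, 1]))
  ds <- mkBinaryDS(X, y)
  ds2 <- mkBinaryDS(2 * X, y)
  l1 <- lambdaPath(ds, "lasso", standardize = FALSE)
  l2 <- lambdaPath(ds2, "lasso", standardize = FALSE)
  expect_equal(l2[1], 2 * l1[1], tolerance = 1e-10)
  lam <- l1[1] / 4
  fA <- penalizedFit(ds, penalty = "lasso", lambda = lam, standardize = FALSE)
  fB <- penalizedFit(ds2, penalty = "lasso", lambda = 2 * lam,
                     standardize = FALSE)
  expect_equal(unname(coef(fB)), unname(coef(fA)) / 2, tolerance = 1e-6)
})

test_that("ridge coefficients shrink toward zero along the path", {
  set.seed(55)
  X <- matrix(rnorm(200), 50, 4)
  y <- rbinom(50, 1, plogis(X[, 1]))
  ds <- mkBinaryDS(X, y)
  lams <- c(0.01, 0.1, 1, 10, 100)
  maxco <- vapply(lams, function(l)
    max(abs(coef(penalizedFit(ds, penalty = "ridge", lambda = l)))),
    numeric(1))
  expect_true(all(diff(maxco) < 0))
  expect_lt(maxco[5], 0.01)
})

test_that("adaptive weights follow |first-stage coefficient| with exclusion", {
  fake <- new("PenalizedFit", family = "logistic", penalty = "lasso",
              intercept = 0,
              coefficients = c(a = 0.5, b = 0, c = -0.2),
              lambda = 0.1, objective = 0, converged = TRUE,
              std = list(center = rep(0, 3), scale = rep(1, 3),
                         clinical = character()),
              penaltyFactors = c(a = 1, b = 1, c = 1), nObs = 10L)
  spec <- adaptiveWeights(fake)
  expect_equal(spec@weights, c(a = 0.5, c = 0.2))
  expect_equal(spec@excluded, "b")

  allzero <- fake
  allzero@coefficients[] <- 0
  expect_error(adaptiveWeights(allzero), class = "penomics_nothing_to_refit")
})

test_that("adaptive-lasso active sets are nested inside lasso active sets", {
  set.seed(66)
  for (rep in 1:3) {
    ds <- simulateDataset(150, 25, support = 1:3,
                          coefficients = c(1.5, -1.5, 1.2),
                          featureModel = "zscore", outcomeModel = "logistic",
                          seed = 660 + rep)
    first <- penalizedFit(ds, penalty = "lasso", lambda = 0.03)
    if (!length(activeSet(first))) next
    spec <- adaptiveWeights(first)
    second <- penalizedFit(ds, weights = spec, lambda = 0.03)
    expect_true(all(activeSet(second) %in% activeSet(first)))
    expect_true(all(coef(second)[spec@excluded] == 0))
    expect_true(kktCheck(second, ds, tol = 1e-6)$ok)
  }
})

test_that("CV tuning is deterministic in the seed and prefers heavy shrinkage on noise", {
  ds <- simulateDataset(120, 15, outcomeModel = "logistic",
                        featureModel = "zscore", seed = 77)
  t1 <- cvTune(ds, "lasso", nFolds = 5, seed = 4)
  t2 <- cvTune(ds, "lasso", nFolds = 5, seed = 4)
  expect_identical(t1$lambdaOpt, t2$lambdaOpt)
  expect_identical(t1$cvCurve, t2$cvCurve)
  t3 <- cvTune(ds, "lasso", nFolds = 5, seed = 5)
  expect_false(identical(t3$cvCurve, t1$cvCurve))

  # pure-noise outcomes: the optimum lies in the largest-lambda third of
  # the path in a majority of seeded replicates
  hits <- 0
  for (s in 1:10) {
    dn <- simulateDataset(100, 10, outcomeModel = "logistic",
                          featureModel = "zscore", seed = 700 + s)
    tn <- cvTune(dn, "lasso", nFolds = 5, seed = s)
    third <- tn$lambdas[ceiling(length(tn$lambdas) / 3)]
    if (tn$lambdaOpt >= third) hits <- hits + 1
  }
  expect_gte(hits, 6)
})

test_that("CV tuning recovers a strong single signal", {
  ds <- simulateDataset(400, 10, support = 1, coefficients = 2,
                        featureModel = "zscore", outcomeModel = "logistic",
                        seed = 88)
  fit <- penalizedFit(ds, penalty = "lasso", lambda = "cv", nFoldsTune = 10,
                      seed = 1)
  expect_true("g0001" %in% activeSet(fit))
})

test_that("degenerate problems raise typed errors", {
  X <- matrix(rnorm(30), 15, 2)
  expect_error(penalizedFit(mkBinaryDS(X, rep(c(0, 1), c(14, 1))),
                            penalty = "lasso", lambda = "cv", nFoldsTune = 10),
               class = "penomics_fold")
  Z <- matrix(0, 15, 2,
              dimnames = list(sprintf("S%02d", 1:15), c("a", "b")))
  dz <- mkBinaryDS(cbind(Z), rep(c(0, 1), c(7, 8)), kind = "binary")
  expect_error(lambdaPath(dz, "lasso"), class = "penomics_degenerate")
  expect_error(penalizedFit(mkBinaryDS(X, rep(c(0, 1), c(14, 1))) ,
                            penalty = "adaptive_lasso", lambda = 0.1),
               class = "penomics_domain")
})
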