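test_that("AUC matches exhaustive pair enumeration and limiting cases", {
  expect_equal(aucScore(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(aucScore(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(aucScore(1:3, c(1, 1, 1)), class = "penomics_degenerate")
})

test_that("AUC is invariant to monotone transforms and flips under negation", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    s <- rnorm(n)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    a <- aucScore(s, l)
    expect_equal(aucScore(exp(s), l), a)
    expect_equal(aucScore(qlogis(plogis(s)), l), a, tolerance = 1e-12)
    expect_equal(aucScore(-s, l), 1 - a)     # tie-free with prob 1
  }
})

test_that("confusion metrics count strictly-greater predictions", {
  perfect <- confusionMetrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(perfect), c(1, 1, 1))
  half <- confusionMetrics(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(half), c(0.5, 0.5, 0.5))
  allneg <- confusionMetrics(c(0.2, 0.3), c(1, 0), threshold = 0.9)
  expect_equal(unname(allneg), c(0.5, 0, 1))
  # boundary: score equal to the threshold predicts 0
  expect_equal(unname(confusionMetrics(0.5, 1, 0.5)[["sensitivity"]]), 0)
  onlyPos <- confusionMetrics(c(0.9, 0.2), c(1, 1), 0.5)
  expect_true(is.na(onlyPos[["specificity"]]))
})

test_that("C-index matches pair enumeration, ties and censoring rules", {
  expect_equal(cIndex(c(2, 4, 6), c(1, 1, 1), c(3, 2, 1)), 1)
  # pairs: (2,4) discordant, (2,6) and (4,6) concordant
  expect_equal(cIndex(c(2, 4, 6), c(1, 1, 1), c(2, 3, 1)), 2 / 3)
  expect_equal(cIndex(c(2, 4, 6), c(1, 1, 1), c(1, 1, 1)), 0.5)
  # a subject censored before every event leaves no comparable pair
  expect_error(cIndex(c(1, 2), c(0, 1), c(1, 2)),
               class = "penomics_degenerate")
  # censored subjects are usable on the later side only
  expect_equal(cIndex(c(1, 2), c(1, 0), c(2, 1)), 1)
  # tied time: event vs censored-at-the-same-time counts as comparable
  expect_equal(cIndex(c(3, 3), c(1, 0), c(5, 1)), 1)
})

test_that("C-index agrees with the survival package on random censored data", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 60
    tm <- round(rexp(n), 2)
    ev <- rbinom(n, 1, 0.7); ev[1] <- 1L
    risk <- rnorm(n)
    mine <- cIndex(tm, ev, risk)
    ref <- survival::concordance(survival::Surv(tm, ev) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("C-index invariance under monotone transforms of the risk score", {
  set.seed(23)
  tm <- rexp(30); ev <- rbinom(30, 1, 0.8); ev[1] <- 1L
  risk <- rnorm(30)
  expect_equal(cIndex(tm, ev, risk), cIndex(tm, ev, exp(risk)))
})

test_that("true linear predictors score high concordance under strong signal", {
  hits <- 0
  for (s in 1:20) {
    ds <- simulateDataset(500, 3, support = 1, coefficients = 2,
                          featureModel = "zscore", outcomeModel = "cox",
                          seed = 4000 + s)
    yd <- penomics:::.ydataOf(ds)
    lp <- covariates(ds)[, 1] * 2
    if (cIndex(yd$time, yd$event, lp) > 0.7) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("k-fold CV is seed-deterministic and respects nFolds = 1", {
  ds <- simulateDataset(120, 10, support = 1, coefficients = 1.5,
                        featureModel = "zscore", outcomeModel = "logistic",
                        seed = 12)
  off <- kfoldCV(ds, nFolds = 1, seed = 3)
  expect_false(off@performed)
  a <- kfoldCV(ds, nFolds = 4, seed = 3, nFoldsTune = 5)
  b <- kfoldCV(ds, nFolds = 4, seed = 3, nFoldsTune = 5)
  expect_identical(a@perFold, b@perFold)
  expect_identical(aggregateMetrics(a), aggregateMetrics(b))
  expect_equal(nrow(a@perFold), 4L)
  expect_true(all(aggregateMetrics(a) >= 0 & aggregateMetrics(a) <= 1))
})

test_that("pooled aggregation scores the concatenated held-out predictions", {
  ds <- simulateDataset(120, 8, support = 1, coefficients = 2,
                        featureModel = "zscore", outcomeModel = "logistic",
                        seed = 14)
  byFold <- kfoldCV(ds, nFolds = 4, seed = 2, lambda = 0.05)
  pooled <- kfoldCV(ds, nFolds = 4, seed = 2, lambda = 0.05, pool = TRUE)
  expect_identical(byFold@perFold, pooled@perFold)
  expect_setequal(names(aggregateMetrics(pooled)),
                  names(aggregateMetrics(byFold)))
  # same data, same folds: the two aggregations must broadly agree
  expect_lt(abs(aggregateMetrics(pooled)[["auc"]] -
                aggregateMetrics(byFold)[["auc"]]), 0.1)
})

test_that("stratification failure is reported with the fold named", {
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0L, 1L), c(18, 2))
  ds <- mkBinaryDS(X, y)
  expect_error(kfoldCV(ds, nFolds = 5, seed = 1), class = "penomics_fold")
})

test_that("training-fold corruption canary: test-only corruption leaves pipeline decisions intact", {
  # strong signal in g0001; g0002 pure noise. Corrupting g0002 only in the
  # held-out rows must not change any metric: screening and tuning see
  # training rows only, and g0002 never enters the model.
  ds <- simulateDataset(160, 6, support = 1, coefficients = 2.5,
                        featureModel = "zscore", outcomeModel = "logistic",
                        seed = 21)
  seed <- 31; nFolds <- 4
  base <- kfoldCV(ds, nFolds = nFolds, seed = seed, screen = TRUE,
                  q = 0.05, lambda = 0.08, nFoldsTune = 5)
  yd <- penomics:::.ydataOf(ds)
  folds <- penomics:::.makeFolds(yd$y, nFolds, seed)
  X <- covariates(ds)
  # in fold 1's held-out rows only, make g0002 a perfect copy of the
  # outcome -- a leaky screen computed on all rows would select it and
  # change fold 1's model and metrics
  X[folds == 1, "g0002"] <- yd$y[folds == 1] * 10
  corrupt <- mkBinaryDS(X, yd$y)
  res <- kfoldCV(corrupt, nFolds = nFolds, seed = seed, screen = TRUE,
                 q = 0.05, lambda = 0.08, nFoldsTune = 5)
  # fold 1 trains on untouched rows; its held-out corruption must be inert
  expect_equal(res@perFold[1, ], base@perFold[1, ])
})
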