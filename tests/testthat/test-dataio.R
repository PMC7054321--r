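test_that("well-formed delimited matrices parse with correct shape and values", {
  f <- writeLinesTmp(c("id\tgA\tgB", "s1\t0.5\t-1.2", "s2\t2.5\t0.0",
                       "s3\t-2.3\t1.9"))
  M <- readMolecularMatrix(f, kind = "zscore")
  expect_s4_class(M, "MolecularMatrix")
  expect_equal(dim(covariates(M)), c(3L, 2L))
  expect_equal(sampleIDs(M), c("s1", "s2", "s3"))
  expect_equal(featureIDs(M), c("gA", "gB"))
  expect_equal(covariates(M)["s2", "gA"], 2.5)

  # comma dialect is auto-detected
  fc <- writeLinesTmp(c("id,gA,gB", "s1,1,0", "s2,0,1"))
  Mc <- readMolecularMatrix(fc, kind = "binary")
  expect_equal(featureKind(Mc), "binary")
  expect_equal(unname(covariates(Mc)[1, ]), c(1, 0))
})

test_that("malformed matrices raise distinct, message-bearing errors", {
  dup <- writeLinesTmp(c("id\tgA", "s1\t1", "s1\t0"))
  expect_error(readMolecularMatrix(dup, kind = "binary"),
               class = "penomics_duplicate_ids")
  nonnum <- writeLinesTmp(c("id\tgA\tgB", "s1\t1\tx", "s2\t0\t2"))
  expect_error(readMolecularMatrix(nonnum, kind = "zscore"),
               class = "penomics_non_numeric")
  dom <- writeLinesTmp(c("id\tgA", "s1\t2", "s2\t0"))
  expect_error(readMolecularMatrix(dom, kind = "binary"),
               class = "penomics_binary_domain")
  expect_error(readMolecularMatrix(tempfile(), kind = "binary"),
               class = "penomics_io")
})

test_that("write/read round trip reproduces numeric content bit for bit", {
  set.seed(7)
  M <- mkMatrix(rnorm(12), 4, 3)
  f <- tempfile(fileext = ".tsv")
  writeMolecularMatrix(M, f)
  M2 <- readMolecularMatrix(f, kind = "zscore")
  expect_identical(covariates(M2), covariates(M))
})

test_that("Z-score dichotomization uses the strict |z| > cutoff rule", {
  M <- mkMatrix(c(2.5, -2.3, 1.9, -2.0, 0, 2.0), 3, 2)
  B <- binarizeZscores(M, cutoff = 2)
  expect_equal(featureKind(B), "binary")
  v <- covariates(B)
  expect_equal(unname(v[, 1]), c(1, 1, 0))  # 2.5 and -2.3 abnormal, 1.9 not
  expect_equal(unname(v[, 2]), c(0, 0, 0))  # -2.0, 0, 2.0 all boundary/normal
  expect_equal(dimnames(v), dimnames(covariates(M)))

  Z <- mkMatrix(rep(0, 6), 2, 3)
  expect_true(all(covariates(binarizeZscores(Z)) == 0))
  expect_error(binarizeZscores(M, cutoff = 0), class = "penomics_domain")
  expect_error(binarizeZscores(binarizeZscores(M)), class = "penomics_kind")
})

test_that("prevalence filter keeps exactly the features at or above the fraction", {
  X <- matrix(0, 100, 3,
              dimnames = list(sprintf("S%03d", 1:100), c("a", "b", "c")))
  X[1, "a"] <- 1                 # prevalence 0.01
  X[1:2, "b"] <- 1               # prevalence 0.02
  M <- molecularMatrix(X, "binary")
  expect_equal(featureIDs(prevalenceFilter(M, 0.01)), c("a", "b"))
  expect_equal(featureIDs(prevalenceFilter(M, 0.02)), "b")
  expect_error(prevalenceFilter(M, 0.03), class = "penomics_empty_filter")

  # boundary behaviour: tiny fraction keeps any feature with >= 1 positive;
  # fraction 1 keeps only all-ones columns
  X2 <- cbind(X[, 1:2, drop = FALSE], d = rep(1, 100))
  M2 <- molecularMatrix(X2, "binary")
  expect_equal(featureIDs(prevalenceFilter(M2, 1e-9)), c("a", "b", "d"))
  expect_equal(featureIDs(prevalenceFilter(M2, 1)), "d")
})

test_that("prevalence filtering commutes with feature reordering", {
  set.seed(11)
  X <- matrix(rbinom(300, 1, 0.15), 30, 10,
              dimnames = list(sprintf("S%02d", 1:30), sprintf("g%02d", 1:10)))
  M <- molecularMatrix(X, "binary")
  keepA <- featureIDs(prevalenceFilter(M, 0.1))
  perm <- sample(ncol(X))
  Mp <- molecularMatrix(X[, perm], "binary")
  keepB <- featureIDs(prevalenceFilter(Mp, 0.1))
  expect_setequal(keepA, keepB)
})

test_that("alignment restricts to the sample-ID intersection and reports drops", {
  X <- matrix(rnorm(10), 5, 2,
              dimnames = list(paste0("s", 1:5), c("gA", "gB")))
  M <- molecularMatrix(X, "zscore")
  out <- binaryOutcome(paste0("s", c(1, 3, 5)), c(1, 0, 1))
  ds <- alignDataset(M, out)
  expect_equal(sampleIDs(ds), c("s1", "s3", "s5"))
  expect_equal(S4Vectors::metadata(ds)$dropped$matrix, c("s2", "s4"))
  expect_equal(unname(covariates(ds)["s3", ]), unname(X["s3", ]))
  expect_equal(SummarizedExperiment::colData(ds)$status, c(1L, 0L, 1L))

  outAll <- binaryOutcome(paste0("s", 1:5), c(1, 0, 1, 0, 1))
  expect_equal(ncol(alignDataset(M, outAll)), 5L)
  disjoint <- binaryOutcome(paste0("t", 1:3), c(1, 0, 1))
  expect_error(alignDataset(M, disjoint), class = "penomics_no_overlap")
})

test_that("clinical tables parse into outcomes and numeric covariates", {
  f <- writeLinesTmp(c("sample_id\ttime\tevent\tage",
                       "s1\t5.2\t1\t63", "s2\t3.1\t0\t58", "s3\t7.4\t1\t70"))
  cl <- readClinicalTable(f)
  expect_s4_class(cl$outcome, "SurvivalOutcome")
  expect_equal(cl$outcome@time, c(5.2, 3.1, 7.4))
  expect_equal(colnames(cl$clinical), "age")

  fb <- writeLinesTmp(c("sample_id,status", "s1,1", "s2,0"))
  expect_s4_class(readClinicalTable(fb)$outcome, "BinaryOutcome")
  bad <- writeLinesTmp(c("sample_id\tfoo", "s1\t1"))
  expect_error(readClinicalTable(bad), class = "penomics_malformed_header")
})

test_that("container validity catches bad outcomes and matrices", {
  expect_error(binaryOutcome(c("a", "b"), c(1, 1)))        # one class only
  expect_error(survivalOutcome(c("a", "b"), c(1, -2), c(1, 0)))  # negative time
  expect_error(survivalOutcome(c("a", "b"), c(1, 2), c(0, 0)))   # no events
  expect_error(molecularMatrix(matrix(c(0, 2), 1, 2,
                                      dimnames = list("s", c("a", "b"))),
                               "binary"))                  # value outside {0,1}
})
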