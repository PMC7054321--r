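`%||%` <- function(a, b) if (is.null(a)) b else a

.err <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "penomics_error")))
}

.expit <- function(x) 1 / (1 + exp(-x))

.logit <- function(p) log(p / (1 - p))

# Evaluate expr with a local RNG state seeded at `seed`; the caller's
# .Random.seed is untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stratified fold assignment: indices of each stratum are shuffled and dealt
# round-robin so every fold sees both outcome classes / events where possible.
.makeFolds <- function(strata, nFolds, seed) {
  n <- length(strata)
  folds <- integer(n)
  .withSeed(seed, {
    for (lv in unique(strata)) {
      idx <- which(strata == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

# Polynomial rolling hash of a deparsed object; used to stamp pipeline
# outputs so re-runs with the same config are recognizable.
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
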