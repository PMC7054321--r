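---
title: "Penalized analysis of high-dimensional molecular alterations"
author: "penomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized analysis of high-dimensional molecular alterations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penomics)
```

# Scope and model

`penomics` analyses a samples-by-features matrix of molecular covariates —
0/1 mutation indicators or continuous expression Z-scores — against a binary
clinical outcome or a right-censored survival outcome. Because the number of
features M routinely exceeds the number of samples n, ordinary maximum
likelihood is unusable and the package fits penalized regressions instead.

For a binary outcome $y_i \in \{0,1\}$ with covariate row $x_i$, the
logistic model $\log\{p_i/(1-p_i)\} = \beta_0 + x_i\beta$ is fitted by
minimizing

$$\frac{1}{n}\,\ell(\beta_0, \beta) \;+\; \lambda \sum_{j=1}^{M} P(\beta_j),$$

where $\ell$ is the negative binomial log-likelihood and $P$ is
$\beta_j^2$ (ridge), $|\beta_j|$ (lasso), or $|\beta_j|/w_j$ (adaptive
lasso) with weights $w_j = |\hat\beta_j^{\text{lasso}}|$ taken from a
first-stage lasso fit. For survival outcomes $(Z_i, \delta_i)$ the same
penalties are attached to the negative log partial likelihood of the Cox
proportional-hazards model $h(t \mid x) = h_0(t)\,e^{x\alpha}$. The lasso
and adaptive lasso set coefficients exactly to zero and therefore perform
variable selection; the adaptive weights sharpen that selection, and any
feature with a zero first-stage coefficient receives an infinite penalty,
so the adaptive active set is nested inside the lasso active set by
construction.

The objective is scaled by $1/n$: a penalty level $\lambda$ here
corresponds to $n\lambda$ for the unscaled log-likelihood form. The scaled
form keeps $\lambda$ paths comparable across sample sizes and is the
convention of pathwise solvers in this field.

Around the penalized core the package provides the stages of a complete
workflow: delimited-text input with validation, Z-score dichotomization and
prevalence filtering, optional univariate screening with
Benjamini–Hochberg false discovery rate control, cross-validated tuning of
$\lambda$, post-selection ("selective") p-values for the selected features,
k-fold cross-validation of prediction power, and a multivariate model
report with exponentiated effect sizes. `runPipeline()` wires the stages
together; each stage is equally usable on its own.

# Preprocessing conventions

* **Abnormality rule.** A Z-score is abnormal when $|z| > c$ with $c = 2$
  by default. The inequality is strict: $z = \pm 2$ counts as normal. This
  is the literal reading of the usual "above 2 or below −2" convention;
  with continuous scores the boundary carries no probability mass, so the
  choice is inconsequential in practice but is pinned down and tested.
* **Prevalence filter.** Only features altered in at least a fraction
  $f$ of samples are kept ($\geq$, not $>$): 1% is the conventional
  default for mutation indicators and 2% for expression abnormality
  indicators. Screening out near-constant indicators stabilizes every
  downstream fit.
* **Expression coding.** Z-score matrices are dichotomized into
  abnormality indicators before modelling by default (`binarize = TRUE` in
  `runConfig()`), which matches the "abnormally expressed" reading of such
  analyses; setting `binarize = FALSE` keeps the continuous scores, which
  are then standardized internally for penalization.
* **Missing cells** are rejected with a typed error. An explicit
  `dropMissingFeatures = TRUE` flag removes affected features instead.
  Imputation is deliberately out of scope: silently imputing molecular
  matrices changes the estimand.

# Screening

With many features it is common to screen before fitting: each feature is
tested univariately (logistic or Cox regression, two-sided Wald test) and
the Benjamini–Hochberg step-up rule is applied at a default FDR threshold
of $q = 0.05$. Both the raw step-up selection and the monotone BH-adjusted
q-values are reported; the two formulations select identical sets, which
the test suite verifies against a brute-force enumeration of the step-up
definition. Wald tests are used because thousands of univariate fits make
likelihood-ratio tests needlessly expensive at screening precision.
Zero-variance features, non-converged fits and perfectly separated
logistic fits are flagged with missing p-values; they are excluded from
the multiplicity correction and can never be selected — a conservative
default for a screening step. Clinical covariates can be included,
unpenalized, in every univariate model via `includeClinical = TRUE`
(off by default).

# Solver

The penalized objectives are minimized by iteratively reweighted least
squares with cyclic coordinate descent on the working response
(soft-thresholding for the $\ell_1$ penalties), the standard architecture
for this model class. Numerical choices that matter:

* **Standardization.** Continuous covariates are standardized to unit
  (population) variance internally and coefficients back-transformed;
  binary 0/1 covariates are left unstandardized by default so that an
  alteration-indicator coefficient remains "effect of carrying the
  alteration" (`standardize` overrides either way). The penalty applies on
  the internal scale.
* **Ties.** The Cox partial likelihood uses the Breslow approximation,
  consistent with pathwise solvers and verified against explicit risk-set
  summation.
* **Path.** 100 log-spaced $\lambda$ values from $\lambda_{\max}$ (the
  smallest value nulling the whole lasso solution, computed from the
  null-model gradient) down to a ratio of $10^{-2}$ when $M > n$, else
  $10^{-3}$. Ridge, which never produces exact zeros, reuses the same grid
  scaled up by 100 so its strong end shrinks comparably.
* **Early termination.** The path stops once the fit essentially saturates
  (over 99.9% of null deviance explained, a relative deviance improvement
  below $10^{-5}$, any coefficient beyond 5 on the standardized scale, or
  an exhausted sweep budget). The guard exists because quasi-separated
  logistic/Cox fits at the weak end of the path diverge slowly and carry
  no statistical information; later grid points reuse the last solution.
* **Convergence.** Relative coefficient change below $10^{-7}$ (final
  fits), with a budget of $10^5$ coordinate sweeps; exceeding the budget
  flags the fit as non-converged rather than returning silently. Path/CV
  fits use $10^{-5}$, which is far below the noise level of a CV
  criterion; the IRLS outer loop for Cox contracts only linearly under
  the diagonal-Hessian working approximation, so the looser tolerance
  matters for speed. Every final $\ell_1$ fit can be certified by
  `kktCheck()`, which recomputes the subgradient conditions at the
  returned solution.
* **Tuning.** `cvTune()` uses 10-fold cross-validation, stratified by
  outcome class (logistic) or event indicator (Cox), minimizing held-out
  binomial deviance or the Verweij–van Houwelingen cross-validated
  partial-likelihood deviance. Ties at the minimum resolve to the largest
  (most parsimonious) $\lambda$. The 10-fold choice concerns tuning only;
  the prediction-power report defaults to 5 folds, and a fold count of 1
  explicitly disables that validation.
* **Degenerate inputs.** Single-class outcomes, event-free survival data,
  all-zero covariate matrices, folds that lose an outcome class, and empty
  post-screening feature sets all raise typed errors (or, in the pipeline,
  a clean early stop) rather than propagating NaNs.

# Post-selection inference

Ordinary p-values computed after lasso selection are invalid: the same data
chose the model. For a fixed $\lambda$, the lasso selection event
$\{$active set $E$, signs $s\}$ is a polyhedron $\{A y \le b\}$ in the
response, and conditionally on it any linear statistic $\eta^\top y$
follows a truncated Gaussian law, giving an exact two-sided pivot. The
package implements this for the Gaussian case and extends it to logistic
and Cox fits by one-step linearization: the IRLS working response and
weights at the solution define a weighted-least-squares lasso whose
solution is the fit itself, and the event is encoded on that working
problem. The noise scale of the working problem is fixed at 1 (the GLM
working-model convention); for the pure Gaussian interface the scale is
estimated from full least-squares residuals when $n > p$. Adaptive
penalties are absorbed by rescaling design columns by the penalty factors,
which turns the weighted event back into a standard lasso event.
Unpenalized columns (intercept, clinical covariates) are projected out
before the event is encoded.

Two approximations are inherited knowingly: inference is performed at the
CV-chosen $\lambda$ although the theory conditions on a fixed one, and the
logistic/Cox linearization is a working-model approximation rather than an
exact conditional law. The calibration that is actually guaranteed — and
tested — is on the Gaussian working problem, where null selective p-values
are uniform; the naive refit z-tests are demonstrably anti-conservative in
the same simulation. Degenerate truncation intervals (width below
$10^{-10}$) yield flagged missing p-values.

# Prediction-power validation

`kfoldCV()` estimates out-of-sample performance of the *entire* configured
pipeline: screening and tuning are re-run inside every training fold, so no
information from held-out samples can leak into selection — a property the
test suite probes with a corruption canary. Reported metrics are accuracy,
sensitivity, specificity (strict `score > threshold` rule, default 0.5 on
the probability scale) and Mann–Whitney AUC for binary outcomes, and
Harrell's concordance for survival outcomes; aggregates are unweighted
means over folds (per-fold values are retained in the report). The
threshold and its scale are configurable because published thresholds are
sometimes stated on the log-odds scale — a threshold of 0.34 on the linear
predictor, say, is *not* a probability of 0.34. AUC is stored in
$[0,1]$ and multiplied by 100 only for display.

# Synthetic data

`simulateDataset()` generates the inputs the pipeline assumes: independent
Bernoulli alteration indicators with per-feature prevalences drawn once
from 1–10% (the typical per-gene mutation range) or standard-normal
Z-scores (≈4.6% of entries abnormal at $|z|>2$); binary outcomes from a
sparse logistic model; survival times from an exponential
proportional-hazards model with independent exponential censoring. The
exponential/exponential choice gives closed-form control of the censoring
fraction — the default censoring rate, $3/7$ of the baseline hazard,
targets ≈30% censoring under the null, a realistic cohort figure. The
ground truth (support, coefficients, achieved censoring) travels with the
dataset and is written as a JSON sidecar by `writeDataset()`.

What the generator does *not* emulate: correlated features (linkage or
co-expression blocks), non-proportional hazards, informative censoring,
batch structure, and measurement error. Passing tests therefore
demonstrate correctness of the procedures under the stated generative
assumptions, not robustness of the method on any particular cohort.

# Worked example

```{r example, eval = FALSE}
ds <- simulateDataset(300, 50, support = 1:3,
                      coefficients = c(1.5, -1.5, 1.2),
                      featureModel = "binary", prevalence = 0.2,
                      outcomeModel = "cox", seed = 1)
sr  <- screenFeatures(ds, q = 0.05)
fit <- penalizedFit(applyScreen(ds, sr), penalty = "lasso", lambda = "cv",
                    seed = 1)
inf <- selectivePvalues(fit, applyScreen(ds, sr))
effectSizes(fit, inference = inf)      # coefficients and hazard ratios
kfoldCV(ds, nFolds = 5, seed = 1, screen = TRUE)
```

# Problem sizes

The package's own simulations are sized for single-workstation use:
recovery studies at $n = 400$, $M = 100$ with 10-fold tuning; calibration
studies at $n = 100$, $M = 10$ with hundreds of replicates; null
validation at $n = 200$. These sizes were chosen so that each study's
Monte-Carlo error is small relative to the property being checked.

# Limitations

* No elastic-net mixing, group or fused penalties.
* No baseline-hazard estimation: Cox models rank by linear predictor only,
  so absolute survival probabilities are out of scope.
* Selective inference provides p-values, not confidence intervals, and for
  logistic/Cox it is the linearized approximation described above.
* The CLI and pipeline read pre-tabulated delimited matrices; variant-file
  (VCF/MAF) parsing and cohort download clients are out of scope.
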