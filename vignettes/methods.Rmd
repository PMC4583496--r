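---
title: "Benchmarking missing-data strategies for risk-model validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking missing-data strategies for risk-model validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missbench)
```

## The problem

External validation of a clinical risk prediction model asks how well a
previously published logistic score discriminates and calibrates in a new
population. Real validation cohorts have missing values on predictors and
sometimes on the outcome, and the analyst must choose a handling strategy
before any performance metric can be computed. The choice is not neutral:
restricting to complete cases shrinks the effective sample (widening every
confidence interval and potentially selecting a biased subsample), while
imputation strategies differ in how much of the predictor-outcome structure
and of the imputation uncertainty they preserve.

missbench quantifies this choice. It runs the same set of logistic risk
models through five strategies — complete-case deletion, unconditional
mean/mode ("simple") imputation, conditional mean imputation, stochastic
regression imputation, and multiple imputation by chained equations (MICE)
— and reports discrimination and calibration before and after intercept
recalibration, in a grid of model x method x calibration-state cells. The
motivating application is screening for undiagnosed diabetes in a
community-based South African cohort; because such cohorts are generally
not deposited, the package ships a synthetic generator that emulates that
study's variable distributions, missingness profile, and outcome
prevalence, so every stage is testable against a known truth.

## The synthetic cohort and what it does (and does not) emulate

`bellville_default_config()` encodes the study conditions:

* Continuous variables are truncated normals with the study's reported
  means and SDs — age 51.9 (15.0) years, BMI 29.7 (7.2) kg/m^2, waist
  circumference 95.8 (15.5) cm, SBP 124.3 (20.2) and DBP 76.0 (12.9)
  mmHg. Truncation bounds are physiologic (BMI 12–70, waist 40–200, SBP
  70–260, DBP 40–160). Age is truncated at 18–95 rather than the
  recruitment window 35–65: no distribution on a 30-year interval can have
  a 15-year SD, so the printed moments — which are what the generator is
  anchored to — are only attainable with a wide bound, and the reported
  sample indeed included participants outside the target window.
* BMI–waist (rho = 0.5) and SBP–DBP (rho = 0.6) are coupled through a
  Gaussian copula; other pairs are independent. The source study reports
  no correlation structure; these two pairs are physiologically coupled
  and give the conditional models something to work with.
* Binary and categorical prevalences are the observed shares (female
  76.5%, antihypertensive medication 35.4%, corticosteroids 1.2%, family
  history 7.5–15.3% across the four indicators, smoking
  current/past/no = 42.6/10.3/47.1%).
* The outcome is drawn from a known logistic model on age, BMI, waist
  circumference, maternal family history and antihypertensive medication.
  The slopes were fixed a priori at plausible epidemiologic magnitudes
  (e.g. 0.035 per year of age, 0.5 for maternal history); the intercept
  (-6.08) was then solved numerically so that the implied outcome
  prevalence equals the study's 15.1%.
* Default missingness is MCAR at the study's per-variable rates (family
  history 24.9–25.1%, smoking 6.1%, outcome 0.7%, all others below 5%).

What the generator does **not** emulate: the real cohort's missingness was
strongly patterned (the four family-history items were typically missing
together, which is why the real complete-case sample was far larger than
the MCAR independence product), predictors beyond the two configured pairs
are uncorrelated, and the true outcome process is exactly logistic in the
generator while reality is not. Passing tests on this cohort therefore
demonstrate the correctness and the qualitative behaviour of the machinery
— not that any particular published model is well calibrated in any real
population.

## Amputation mechanisms

`apply_missingness()` masks cells of a complete table; it never alters a
value, so un-masking reproduces the input exactly. MCAR masks each cell
independently at the target rate. MAR masks with probability
`expit(a + w' z)` where `z` are standardised fully observed drivers and
`w` the configured weights; the intercept `a` is calibrated by bisection
so the marginal rate matches the target (the root is found to 1e-10, so
realised rates deviate only by binomial noise). MNAR is MAR with the
variable's own pre-amputation value as the driver. MAR drivers may not
themselves be amputed in the same pass — the configuration constructor
rejects such cycles.

## The five strategies

All conditional models use every other variable **plus the outcome** as
predictors, and the outcome itself is imputable. Fits are linear for
continuous targets, logistic for binary, multinomial for categorical
(`nnet::multinom`, run under a fixed local RNG state because its random
starting weights would otherwise make deterministic methods
rerun-unstable). A model that cannot be fitted or used for prediction
(singularity, a factor level unseen in the fitting rows) falls back to an
unconditional mean/mode fill (deterministic methods) or an observed-value
draw (stochastic methods); every fallback is logged in the result, never
silently absorbed, and never a crash — benchmark sweeps must complete.

* **deletion** (`complete_case`): keeps only fully observed rows. The
  label follows the benchmarking literature's "pairwise deletion" usage,
  but the behaviour is listwise/complete-case: a single reduced sample is
  produced, which is what a single reported reduced N implies.
* **simple** (`simple_impute`): observed column mean for continuous,
  observed majority category for binary/categorical (ties broken by the
  first category in schema order). Column means are preserved exactly;
  SDs can only shrink.
* **conditional** (`conditional_mean_impute`): per-variable regressions
  fitted on the fully complete rows; only cells whose row is complete on
  every predictor are filled, so columns keep "varied" effective lengths.
* **stochastic** (`stochastic_regression_impute`): the same regressions,
  but continuous fills add a residual draw `N(0, sigma_hat^2)` with the
  coefficients used as estimated — no parameter-uncertainty draw, the
  `norm.nob` semantics — and categorical/binary fills are drawn from the
  fitted class probabilities. Cells whose rows are incomplete on
  predictors are completed by one chained sweep seeded from unconditional
  observed-value draws, so the output is a full table.
* **mice** (`mice_impute`): fully conditional specification. Missing
  cells are initialised with random observed-value draws; variables are
  visited in schema order for `iterations` sweeps; each visit refits the
  conditional model on the rows where the target was originally observed
  (with all other variables as currently completed) and redraws the
  originally missing cells. The chain draws parameters as well as
  residuals — posterior `sigma^2` and coefficients for continuous
  targets, a large-sample normal coefficient draw for logistic ones — so
  the imputation is *proper*; without the parameter draw, between-
  imputation variance is understated and pooled intervals undercover.
  Categorical targets use class-probability draws (a documented
  approximation). The chain is repeated `m` times with independent
  sub-seeds.

Defaults: `m = 5` (matching the benchmark design the package mirrors),
`iterations = 10` (a standard FCS burn-in; the chain's fitted
distributions stabilise well before that at these missingness levels),
visit order = schema order.

## Pooling and metrics

`rubin_pool()` combines m estimates and variances: pooled estimate
`q_bar = mean(q_k)`, within-variance `w = mean(v_k)`, between-variance
`b = var(q_k)`, total `t = w + (1 + 1/m) b`, large-sample degrees of
freedom `(m-1)(1 + w/((1+1/m)b))^2` (infinite when `b = 0`; the
small-sample correction is deliberately out of scope).

Per completed dataset, `evaluate_performance()` computes on the common
scored subset (rows with a prediction and an observed outcome):

* **C-statistic**: midrank (Mann–Whitney) formulation, exactly equal to
  exhaustive pair enumeration with ties counting one half; 95% CI from
  the DeLong placement-value variance (Hanley–McNeil available via
  `ci_method` for sensitivity).
* **E/O ratio**: sum of predicted probabilities over observed events;
  95% CI treats O as Poisson on the log scale,
  `ratio * exp(+/- 1.96/sqrt(O))`, which keeps bounds positive. This is
  the one place where agreement with other software's intervals can
  legitimately differ, since several Poisson-CI constructions coexist.
* **Brier score** and **Yates slope** by their definitions; the slope is
  bounded in [-1, 1] under its definition as a difference of mean
  probabilities.

Across multiply imputed datasets, `pool_reports()` pools point estimates
as arithmetic means and interval half-widths through Rubin's total
variance on a working scale — logit for the C-statistic (delta method on
the DeLong variance) and log for E/O (Poisson variance 1/O) — with a
t-quantile on the Rubin degrees of freedom. When the m reports are
identical (zero between-imputation variance) pooling returns the input
unchanged. The working scales are a design choice; the pooling rule
itself does not prescribe one.

## Risk models and recalibration

Models are declarative: an intercept plus additive logit-scale terms with
`identity`, `indicator(category)`, `band(breaks, scores)` and `product`
transforms, stored in YAML so users can paste published coefficients
without touching code. The five shipped specs (Cambridge, Kuwaiti, Omani,
Rotterdam, simplified Finnish) reproduce the published models' predictor
structures — every one includes age — but carry clearly marked
placeholder coefficients; substitute the published values for substantive
work. Rows missing any required predictor are counted unscorable and
excluded from that cell's metrics (with the effective n reported), since
partially informed scoring would silently mix models.

Numerical choices: the linear predictor is clamped to +/-35 before
`expit`, so probabilities are strictly inside (0, 1);
`recalibrate_intercept()` finds the additive shift by bisection on
[-20, 20] (expected events are continuous and strictly increasing in the
shift) to `|E - O| <= 1e-6 O`. The shift is rank-preserving, so the
C-statistic is bit-identical before and after — a joint property the
tests assert.

## Orchestration and reproducibility

`run_comparison()` executes exclusion, missingness summary, each method,
scoring, evaluation, per-dataset recalibration and re-evaluation, and —
for MICE — per-dataset metric panels followed by pooling, retaining the
per-dataset sub-table. Every stage derives its own sub-seed from the
master seed by hashing the stage label, so adding a method never perturbs
another method's draws and reruns are bit-identical. Cells that fail
(e.g. a single-class outcome after deletion on a tiny cohort) are
reported as NA with the reason, and the rest of the grid completes.

## Problem sizes used in the shipped checks

The test-suite and acceptance runs use the generator at the study's
analysis size (n = 1083) for the benchmark grid and deletion-penalty
contrast (50 cohorts), n = 2000 with 25% MAR for the chained-equations
coverage study (100 replicates, m = 5), and n up to 10000 for marginal
and rate calibration checks. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bounds while keeping a full run in well
under a minute of CPU.

## Known limitations

* The shipped model coefficients are placeholders; absolute performance
  numbers from the default registry are not comparable to published
  validations of the real scores.
* MCAR-by-default missingness understates the pattern correlation of
  real cohorts; configure MAR/MNAR entries to study structured
  missingness.
* Multinomial conditional draws do not draw parameters, so categorical
  between-imputation variance is slightly understated.
* The E/O interval uses one of several defensible Poisson constructions.
* Rubin degrees of freedom use the large-sample form; with very small m
  and n the pooled intervals are mildly anti-conservative.
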