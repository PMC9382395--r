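---
title: "Class imbalance corrections and the calibration of risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class imbalance corrections and the calibration of risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imbcalib)
```

## The question

Clinical prediction models for a binary outcome are usually developed in
cohorts where events are much rarer than nonevents. A popular reflex is to
"fix" this class imbalance before model training by resampling: random
undersampling of the majority class (RUS), random oversampling of the
minority class (ROS), or synthetic minority oversampling (SMOTE). These
techniques are motivated by classification accuracy, but risk models are
used through their *probabilities* — to counsel patients and to make
treatment decisions at clinically chosen risk thresholds. This package
provides the machinery to study what artificial balancing does to those
probabilities: a calibrated synthetic data generator, the corrections, the
models, a full set of validation metrics, and a factorial Monte Carlo
engine.

The headline phenomenon is easy to state. Balancing a training set raises
the apparent event fraction from \(\phi\) to 1/2, which shifts the intercept
of a logistic model by roughly \(\mathrm{logit}(1/2)-\mathrm{logit}(\phi)
= -\mathrm{logit}(\phi)\) while leaving discrimination essentially
untouched. Models trained on balanced data therefore *systematically
overestimate* risk when applied to the real population, more severely the
rarer the event, and a simple intercept recalibration on the original data
undoes most of the damage.

## Data-generating mechanism

Synthetic cohorts are drawn from a logistic mechanism with \(p\)
independent standard-normal predictors of equal strength:

\[
P(Y=1\mid x) = \mathrm{logit}^{-1}\Big(b_0 + \beta \sum_{j=1}^p x_j\Big).
\]

`calibrate_generator(p, event_fraction, cstat)` solves for \((b_0, \beta)\)
so that the marginal event fraction and the c-statistic of the true linear
predictor hit their targets (default c-statistic 0.75). Because the linear
predictor is Normal with mean \(b_0\) and standard deviation
\(s=\beta\sqrt{p}\), both targets depend only on \((b_0, s)\); a corollary
worth testing is that \(\beta\sqrt p\) is invariant in \(p\) at fixed
targets. The two moments are evaluated by 80-node Gauss–Hermite quadrature
and the system is solved by nested bisection-safe root-finding: the inner
solve finds \(b_0\) for the prevalence at fixed \(s\) (monotone in
\(b_0\)), the outer finds \(s\) for the c-statistic (monotone in \(s\)).
Calibration is therefore deterministic; verification against the targets is
done stochastically in the test suite with large fixed-seed Monte Carlo
draws. Achieved quadrature values must be within 0.001 (prevalence) and
0.005 (c-statistic) of target, tighter than anything asserted downstream.

The factorial study grid crosses training size \(N \in \{2500, 5000\}\),
dimension \(p \in \{3, 6, 12, 24\}\) and event fraction
\(\phi \in \{0.3, 0.1, 0.01\}\) — 24 scenarios. Each scenario evaluates all
replicates against a single fixed test set drawn from the same mechanism
(100,000 rows in the full design). Seeds are derived deterministically per
(scenario, replicate), with replicate 0 reserved for the test set, so
results are reproducible regardless of execution order and interrupted runs
can resume.

## Corrections

All three corrections balance the classes exactly, defining the minority
class per dataset as the rarer outcome value:

* **RUS** keeps every minority row and a uniform random subset of majority
  rows of equal size. It fabricates nothing but discards most of the data
  when imbalance is severe.
* **ROS** resamples minority rows with replacement up to the majority
  count; every added row is an exact duplicate.
* **SMOTE** interpolates: for a minority row \(x_i\), one of its \(k=5\)
  nearest minority neighbours \(x_{nn}\) (Euclidean distance, ties broken
  by row index) is chosen uniformly, and a synthetic row
  \(x_i + u\,(x_{nn}-x_i)\), \(u\sim U(0,1)\), is added. Where the number
  of rows needed is not a multiple of the minority count, synthetic rows
  are allocated evenly with a random subset receiving one extra — the
  original algorithm leaves this unspecified, and exact balance keeps the
  downstream bookkeeping simple. For ordinal predictors the synthetic
  values can be rounded back to the observed levels (`round_cols`), which
  the simulation grid never needs (all predictors continuous) but the
  case-study fixture exercises.

## Models

`fit_logit()` fits either maximum-likelihood logistic regression (SLR) or
ridge (L2) logistic regression. The ridge penalty applies to slopes only,
on the internally standardized scale, with coefficients mapped back to the
original scale; \(\lambda\) is chosen by 10-fold cross-validated binomial
deviance over 30 grid points log-spaced on \([10^{-4}, 10^{2}]\), folds
stratified by outcome (at 1% events unstratified folds frequently contain
none), and the model is refit on all data at the selected value. The
solver is a warm-started iteratively-reweighted least squares path written
with RcppArmadillo; it uses the same objective convention as glmnet, and
the test suite verifies coefficient agreement with glmnet to 1e-6 at fixed
\(\lambda\) and that identical fold assignments select the identical
\(\lambda\). The exact grid and loss are design choices of this package:
they are exposed through the `lambda` argument rather than hidden.

(Quasi-)complete separation matters at the smallest cells — RUS at 1%
events with \(N=2500\) and \(p=24\) trains on roughly 25 events versus 25
nonevents. SLR fits flag separation when all fitted probabilities are
numerically 0/1 or any standardized coefficient exceeds 20; flagged models
are still returned and evaluated, and the engine tallies the flags.
Ridge fits remain finite under separation, which is part of the story the
study tells.

Continuous predictors can be expanded with restricted cubic splines
(Harrell's truncated-power parameterization; 3 knots at the 0.10/0.50/0.90
quantiles, adding one nonlinear term per variable, linear beyond the
boundary knots). The simulation grid is linear by construction, so splines
are exercised by the synthetic case-study fixture instead.

`recalibrate()` implements intercept-only logistic recalibration: the
logit of the model's estimated probabilities enters as an offset and only
the intercept is refit. In the pipeline, recalibration always uses the
*original imbalanced* training data — recalibrating on the balanced data
would be a no-op on the very bias being corrected. Probabilities are
clipped to \([10^{-10}, 1-10^{-10}]\) before any logit anywhere in the
package; at 1% prevalence, test-set logits are extreme enough that this
policy is load-bearing.

## Metrics

All metrics in the validation battery are computed on a held-out test set:

* **AUROC** by the rank-sum concordance formulation with midranks (ties
  count 1/2) — identical to enumerating all event/nonevent pairs, which
  the tests do on small inputs.
* **Calibration intercept**: the intercept \(a\) of
  \(\mathrm{logit}\,P(Y=1) = a + LP\) with the model's logit \(LP\) as an
  offset; \(a<0\) means overestimation. **Calibration slope**: the
  coefficient \(b\) of \(\mathrm{logit}\,P(Y=1) = a' + b\,LP\); \(b<1\)
  means predictions too extreme. Both are dedicated Newton iterations
  (score equations are low-dimensional and strictly concave) and are
  verified against `glm` with offset in the tests.
* A **flexible calibration curve**: loess smooth of the outcome against
  \(LP\), mapped back to an evenly spaced probability grid (span 0.75 by
  default; the smoother is applied to \(LP\), not to the probability).
* **Classification** at a risk threshold \(t\) (high risk iff
  \(\hat\pi \ge t\)): accuracy, sensitivity, specificity and the
  confusion counts.
* **Net Benefit** \((TP - \frac{t}{1-t}\,FP)/N\) and decision curves with
  treat-all and treat-none references. Treat-none is 0 by definition and
  treat-all crosses zero exactly at \(t=\) prevalence, which is asserted
  as an identity in the tests.

The engine evaluates classification at \(t=0.5\) for every model and
additionally at \(t=\phi\) (the true event fraction) for models trained on
uncorrected data, where shifting the threshold is the natural alternative
to resampling.

## The simulation engine

`run_replicate()` draws a fresh training set, builds the four training
variants, fits SLR and Ridge on each (8 models), adds intercept-recalibrated
versions of the six corrected models (14 performance records), and
evaluates everything on the scenario's fixed test set. Failures are caught
per model, recorded with their cause, and excluded from summaries — medians
are computed over successful replicates, with error and separation counts
reported alongside, rather than imputing anything. `run_scenario()`
aggregates medians and quartiles per (correction, model, recalibrated)
cell; `run_grid()` runs a list of scenarios resumably;
`summarize_to_table()` binds everything into a tidy long table.

`run_reduced_study()` is the desk-scale preset used by the acceptance
machinery: \(N \in \{2500,5000\} \times p \in \{3,24\}\) with all three
event fractions for uncorrected SLR/Ridge (12 cells), plus the three
\(N=5000, p=3\) cells with corrected Ridge models and their recalibrated
versions; 200 replicates per scenario and 50,000-row test sets. These
sizes keep a full run around a quarter of an hour on one CPU while leaving
the Monte Carlo error of cell medians far smaller than the effects being
measured (the corrected-data calibration intercepts differ from zero by
0.7–4.5 logits). The full design (2000 replicates, 100,000-row test sets,
24 scenarios) is available by configuration.

## What the generator does and does not emulate

The simulation mechanism has independent, homoscedastic, standard-normal
predictors of equal strength and a correctly specified linear logit. Real
cohorts have correlated mixed-type predictors, unequal effects,
nonlinearities and model misspecification. Passing tests therefore
demonstrate the *mechanism* of miscalibration under resampling — a shifted
intercept is forced by the altered class frequencies, not by distributional
quirks — but do not quantify how large the distortion is in any particular
real dataset.

The package ships a synthetic case-study fixture
(`generate_case_study()`) emulating the *structure* of an ovarian-tumour
diagnosis cohort: age in years truncated to 18–59, log-normal lesion
diameter in mm, an ordinal papillation count 0–4, a ~20% event fraction,
and a deliberately curved log-diameter effect so that the spline machinery
is genuinely needed. Its coefficients are fixed constants chosen once (the
intercept by a large Monte Carlo solve for the 20% event fraction); it was
not fit to any real data, and no real-data quantity is asserted against
it.

## Numerical choices and degenerate inputs

* Probability clipping bound \(10^{-10}\), applied before every logit.
* Ridge IRLS convergence: max absolute coefficient change \(<10^{-9}\)
  for final fits, \(<10^{-6}\) inside cross-validation (fold deviances
  are insensitive at that scale); Hessians are refreshed only when chord
  steps stall, which leaves the converged solution unchanged.
* SMOTE requires at least 2 minority rows; \(k\) is clamped to
  minority\(-1\) with a warning when necessary; distance ties break by
  row index for determinism.
* Single-class inputs are errors everywhere (correction and fit
  failures); the engine records them and continues.
* Constant linear predictors make the calibration slope undefined
  (reported `NA`); the intercept-only offset fit handles a degenerate
  constant offset as a plain intercept fit.
* Scenario seeds: `derive_seed(base_seed, scenario_id, replicate)` is an
  integer hash kept below \(2^{31}\); streams for distinct
  (scenario, replicate) pairs are distinct across the whole grid.

## Known limitations

* Only intercept recalibration is implemented; slope recalibration and
  stronger updating methods are out of scope, as are correction variants
  (borderline-SMOTE, class weighting, cost-sensitive learning) and other
  learners (random forests, SVMs, neural networks).
* Event fractions above 0.5 and correlated or non-normal predictors are
  not supported by the generator — deliberately, to keep the mechanism
  interpretable.
* At 1% event fraction the *shared* test set's realized prevalence adds a
  common shift of order \(\pm 0.05\) logits (SE of a logit prevalence at
  50,000 rows) to every replicate's calibration intercept; this is a
  property of the single-test-set design itself, visible even when scoring
  the true generating probabilities, and should be kept in mind when
  reading per-cell medians at the smallest event fraction.

## A worked run

```{r, eval = FALSE}
cfg <- scenario_config(n_train = 2500, p = 3, event_fraction = 0.1,
                       n_reps = 50, n_test = 20000, base_seed = 1)
s <- run_scenario(cfg)
s
```

The printed cell medians show the pattern the package exists to expose:
uncorrected models with calibration intercepts near 0, corrected models
near \(\mathrm{logit}(0.1) \approx -2.2\), and recalibrated corrected
models back near 0, while AUROC barely moves across cells.
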