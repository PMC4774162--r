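---
title: "Semi-supervised survival analysis with L1/2-regularized Cox and AFT models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised survival analysis with L1/2-regularized Cox and AFT models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semisurv)
```

## The problem

High-dimensional survival studies — a few hundred tumour samples, around a
thousand gene-expression covariates — face two compounding difficulties.
First, a large fraction of samples is right-censored: for them only a lower
bound on survival is known, and a supervised Cox risk classifier trained on
complete samples alone discards much of the cohort. Second, the accelerated
failure time (AFT) model, which regresses log survival time on expression,
presumes the samples follow one common time distribution, while clinically
similar tumours are often distinct diseases at the molecular level.

`semisurv` implements a semi-supervised procedure that attacks both problems
at once. An L1/2-penalized Cox model, fitted on the currently usable
(complete) samples, assigns every sample — censored included — to a low- or
high-risk class. Within each class, which is intended to collect
molecularly comparable samples, censored survival times are imputed by a
Kaplan–Meier conditional mean; an L1/2-penalized AFT model then re-estimates
each censored sample's survival time. Re-estimates that do not exceed the
observed censoring time contradict the data ("error estimations") and are
discarded; the rest join the training set as events, and the cycle repeats.
The result is a larger training set, sparser and more accurate gene
selection, and a survival-time predictor for individual patients.

## Models and estimation

### The L1/2 penalty and its half-thresholding operator

Both models are fitted by minimizing loss + penalty with the nonconvex
penalty $\lambda \sum_j |\beta_j|^{1/2}$, which yields considerably sparser
solutions than the lasso while retaining an analytic coordinate-wise
update. The scalar problem $(b - \omega)^2 + \lambda |b|^{1/2}$ is solved
in closed form by `half_threshold()`: zero at or below the boundary
$\frac{\sqrt[3]{54}}{4}\lambda^{2/3}$ (`threshold_boundary()`), and
$\frac{2}{3}\,\omega\left(1 + \cos\frac{2(\pi - \varphi_\lambda(\omega))}{3}\right)$
with $\varphi_\lambda(\omega) = \arccos\!\big(\frac{\lambda}{8}
(\frac{|\omega|}{3})^{-3/2}\big)$ above it.

A calibration detail matters here. The package's solver minimizes the
half-weighted objective
$\frac{1}{2n}\sum_i w_i (y_i - x_i'\beta)^2 + \lambda\sum_j |\beta_j|^{1/2}$,
whose exact scalar subproblem is $\frac12 (b - \omega_j)^2 + \lambda'
|b|^{1/2}$ after standardization. The minimizer of that half-weighted form
is `half_threshold(omega, 2 * lambda')` — the operator's quadratic term
carries no $\tfrac12$ — and the corresponding activation boundary is
$\frac32 \lambda'^{2/3}$. The solver applies the operator at penalty
$2\lambda$ per coordinate, which makes every update the exact global
minimizer of its subproblem and hence the objective non-increasing sweep to
sweep (verified as a test invariant, alongside a brute-force grid oracle
for the operator itself). Features are standardized internally to column
sum of squares $n$ (population scaling, not $n-1$), because that is what
reduces the coordinate update to the scalar problem exactly;
coefficients are always reported back on the original scale.

Because the penalty is nonconvex, the fitted point is a fixed point of the
coordinate operator with non-increasing objective, not a certified global
minimum, and it depends on the iteration convention. The convention is
therefore fixed and documented: cyclic coordinate order, zero
initialization at the top of the penalty path, warm starts downwards along
the path, convergence when the largest coefficient change in a sweep falls
below $10^{-5}$, and ties at the activation boundary resolved to zero.

### Cox fitting, risk classes, and the baseline hazard

`fit_cox_l12()` maximizes the (1/n-scaled) Breslow log partial likelihood
minus the penalty by iteratively reweighted least squares: at the current
linear predictor the gradient and diagonal Hessian of the partial
likelihood define a weighted working response, the inner coordinate-descent
solver handles the penalized quadratic, and the outer loop repeats until
the linear predictor stabilizes (max change below $10^{-4}$, at most 100
outer cycles). Two numerical safeguards are built in. Working weights are
floored at $10^{-5}$ to keep the working response finite in saturated
regions. And because the square-root penalty is not locally Lipschitz at
zero, a shortened step toward a newly activated coordinate can only
increase the penalized objective — so when a full IRLS step increases the
objective and a few halvings do not cure it, the iterate is kept and the
loop stops rather than forcing a spurious "descent". During
cross-validation tuning the outer loop is additionally capped at 25 cycles:
penalties deep in the overfit region converge slowly and are never
competitive under the tuning criterion, so polishing them is wasted work.
For the same reason the IRLS iterations between full convergence checks
sweep only the active coordinates, with a final full sweep confirming the
fixed point.

Ties among event times use the Breslow convention throughout, matching the
Breslow baseline estimator
$\hat H_0(t) = \sum_{t_{(r)} \le t} d_r / \sum_{j \in R_r} e^{\beta'x_j}$
that supplies predicted survival curves
$\hat S(t \mid x) = \exp(-\hat H_0(t)\, e^{\beta'x})$.

`classify_risk()` splits samples at the median prognostic index
$\beta'x$ of the *training* samples (a `"zero"` rule is available). The
median is the default because nothing in the underlying method pins the
class boundary, and the median guarantees both classes are populated on
the training set.

The penalty is tuned by `cv_tune_cox()` with the Verweij–van Houwelingen
cross-validated partial likelihood
$\sum_k \big[\ell(\hat\beta_{-k}) - \ell_{-k}(\hat\beta_{-k})\big]$ over
folds stratified on the event indicator; ties in the criterion go to the
larger (sparser) penalty.

### AFT fitting and conditional-mean imputation

The AFT model is $h(t_i) = \beta_0 + x_i'\beta + \varepsilon_i$ with
$h = \log$ (any monotone transform is accepted; log is the standard choice
for positive times). Censored responses are replaced by the Kaplan–Meier
conditional mean

$$h(t_i^{*}) = \delta_i\, h(t_i) + (1 - \delta_i)\,
\hat S(t_i)^{-1} \sum_{t_{(r)} > t_i} h(t_{(r)})\, \Delta\hat S(t_{(r)}),$$

the expectation of $h(T)$ given $T > t_i$ under the product-limit estimate
(`km_mean_impute()`). The sum runs over event times *strictly* later than
the censored time; a censored time tying an event time uses later events
only. A censored sample beyond the last event time has an empty sum; it
receives $h$(largest event time) — the conventional
redistribute-to-the-right fallback — and is flagged `undefined_tail` so
the semi-supervised loop can exclude it from AFT training.
`cv_tune_aft()` scores held-out mean squared error on the $h$ scale over
*trusted* responses only (observed events by default), so the penalty is
never tuned against fabricated targets.

### The semi-supervised loop

`run_semisupervised()` iterates: (1) tune and fit Cox on the training set
(complete samples plus previously validated imputations entering as events
at their re-estimated times); (2) classify all samples into risk classes;
(3) impute each class's pending censored samples from that class's
training samples; (4) tune and fit the AFT model on the training set plus
the class-imputed samples — the class imputations act as warm-start
responses and are excluded from the held-out tuning loss — then re-predict
every censored sample's time; (5) keep re-estimates strictly above the
censoring time; (6) stop when the validated set repeats or after
`max_iters` (default 5, reflecting that the procedure is meant to be
repeated to a fixed point; in practice the set stabilizes in a few
rounds). Final Cox and AFT models are refit on the terminal augmented set.

Design choices in the loop that were genuinely open, and how they were
resolved:

- *Validated samples enter as events.* The loop's purpose is to convert
  censored samples into usable training data; entering them censored would
  change nothing.
- *AFT re-estimates are authoritative* over the class-wise conditional
  means: the conditional mean is a class-level summary, while the AFT
  prediction uses the sample's own covariates.
- *Cox is retrained every iteration*, because retraining is the only way
  newly validated samples can influence classification.
- *Validation is strict* (`imputed > censored`); equality carries no
  information beyond the censoring itself.
- *Both models see all features.* A configuration switch
  (`restrict_aft_to_cox`) restricts the AFT design to Cox-selected genes,
  but independent selection is the default since the two models answer
  different questions (risk ranking versus time prediction) and are
  expected to select different genes.
- *Degenerate penalties fall back to the sparsest active model.* If the
  tuned penalty selects nothing, classification is impossible at that
  penalty, so the loop takes the largest penalty on the grid with a
  nonempty support.

### Evaluation statistics

`brier_score()` implements the inverse-probability-of-censoring-weighted
squared error with the censoring distribution $\hat G$ estimated by the
Kaplan–Meier method on flipped indicators; weights are evaluated at left
limits $\hat G(t^-)$, and samples with zero weight are excluded with the
denominator adjusted. `integrated_brier()` integrates it exactly as a step
function over the grid of observed times. `concordance_index()` counts
strictly concordant comparable pairs ($t_i < t_j$ with $\delta_i = 1$);
tied predictions are not concordant, and Cox prognostic scores must be
negated so that larger always means longer survival.
`selection_precision()` is correct selections over total selections, with
an empty selection flagged undefined rather than zero.

## The simulator

`simulate_survival()` generates the synthetic study conditions:
equicorrelated Gaussian expression values
$X_{ij} = \gamma_{ij}\sqrt{1-\rho} + \gamma_{i0}\sqrt{\rho}$; survival
times by the Gompertz inverse transform
$y_i = \frac{1}{\alpha}\log\big(1 - \frac{\alpha \log U}{\omega\,
e^{\beta'x_i}}\big)$; and exponential censoring with rate calibrated by
root-finding so the expected censored fraction — computed against the
realized survival times, which is more robust than integrating over the
heavy-tailed time distribution — matches the target. Censoring is
calibrated *within each true-risk subgroup* (samples above/below the
median true linear predictor): under a sparse unit-coefficient signal the
survival times of the two prognosis groups live on completely different
scales, and a single censoring rate would censor almost exclusively the
long-surviving half, which is not the intended design. Ties between
survival and censoring times count as censored (strict inequality in the
event indicator).

Defaults define the study conditions used by the tests and the acceptance
script: $p = 1000$ features, 10 informative with unit coefficients,
$\alpha = \omega = 1$, 40% censoring, $n \in \{100, 200, 300\}$ and
$\rho \in \{0, 0.3\}$. The nonzero coefficient values and the Gompertz
parameters are conventions (the scheme this emulates does not fix them);
unit values are the neutral choice and all are configurable. What the
simulator does *not* emulate about real expression data: heavy-tailed and
heteroscedastic expression distributions, block (pathway) correlation
rather than a single equicorrelation factor, informative censoring, and
measurement batch effects. Passing the simulation study therefore
demonstrates correctness of the machinery and the direction of the
semi-supervised gains, not clinical performance.

Under these unit-coefficient defaults the signal is strong: at $n = 300$
the tuned models recover essentially the whole informative set, with
selection noise (and hence precision below 1) coming from the nonconvex
path's local solutions, and the single/semi contrast is most visible at
the smaller sample sizes where the single Cox model under-selects
severely. The share of censored samples whose re-estimated times fail
validation is substantially larger here than under weaker-signal designs,
because censoring times within the short-lived high-risk class sit close
to the true times and a conditional-mean predictor exceeds them less
often.

## Problem sizes and reproducibility

The packaged experiment (`run_experiment()`, wrapped by
`scripts/acceptance.R`) runs the six $(n, \rho)$ settings at ten
replicates each, with every fit tuned by 5-fold stratified
cross-validation over a 20-point penalty grid spanning
$[0.08, 1] \cdot \lambda_{\max}$ — grid sizes chosen as a sensible
resolution for the nonconvex path, where warm starts make neighbouring
penalties cheap. All randomness flows from one master seed through
deterministic per-replicate seeds, so identical invocations reproduce
identical tables; the unit-test suite exercises the same machinery at
smaller $n$ and $p$.

## Known limitations

- The nonconvex objective makes every fit convention-dependent; a
  different coordinate order or initialization can select a slightly
  different gene set with similar fit quality. Only the documented
  convention is supported.
- The Cox IRLS working problem uses the diagonal of the Hessian; in
  near-saturated regimes (very small penalties, few events) the outer
  loop may stop on the no-descent safeguard rather than the tolerance.
- Breslow tie handling only; no Efron weights, time-varying covariates,
  or stratified baselines.
- The AFT survival-curve predictor (for Brier scores) applies the
  Kaplan–Meier estimate of training residuals, which assumes i.i.d.
  errors on the $h$ scale.
- `km_mean_impute()` is undefined past the last event time; the
  redistribute-to-the-right fallback is flagged, not hidden, and such
  samples never enter AFT training inside the loop.
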