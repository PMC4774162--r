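# semisurv

Semi-supervised survival analysis for high-dimensional, heavily censored
gene-expression data, built on L1/2-regularized Cox and accelerated failure
time (AFT) models.

## The problem

In clinical cancer cohorts the number of genes *p* dwarfs the number of
samples *n*, and a large fraction of samples is right-censored: their event
was never observed, so a supervised Cox risk classifier can train only on
the complete samples and throws the rest away. The AFT model, which predicts
survival time directly, has the opposite problem — imputing censored times
from one pooled survival curve mixes patients whose similar phenotype hides
different molecular diseases.

`semisurv` implements an iterative semi-supervised procedure that couples
the two models so each fixes the other's weakness:

1. fit an L1/2-penalized Cox model
   (argmin −ℓ(β) + λ Σⱼ |βⱼ|^½, with ℓ the Breslow log partial likelihood)
   on the currently usable samples;
2. classify **all** samples into low/high-risk classes by the prognostic
   index β′x (median split);
3. within each risk class — molecularly comparable patients — impute
   censored log-times by the Kaplan–Meier conditional mean
   h(tᵢ*) = Ŝ(tᵢ)⁻¹ Σ_{t₍ᵣ₎>tᵢ} h(t₍ᵣ₎) ΔŜ(t₍ᵣ₎);
4. fit an L1/2-penalized AFT model h(tᵢ) = β₀ + xᵢ′β + εᵢ and re-estimate
   every censored sample's survival time;
5. keep only re-estimates that strictly exceed the observed censoring time
   (the rest are "error estimations"); validated samples join the training
   set as events, and the loop repeats until the validated set stabilizes.

The penalty λ Σ|βⱼ|^½ is handled coordinate-wise by the closed-form
half-thresholding operator with activation boundary (∛54/4)·λ^⅔, and λ is
tuned by stratified 5-fold cross-validation (cross-validated partial
likelihood for Cox, held-out MSE on trusted responses for AFT). Prediction
quality is measured by the censoring-weighted integrated Brier score and
the concordance index; gene selection by precision against a known support.

A Gompertz inverse-transform simulator (`simulate_survival()`) generates
equicorrelated expression data with 10 informative genes among p = 1000 and
calibrated ~40 % censoring — the package's synthetic study conditions.

## Worked example

```r
library(semisurv)

sim <- simulate_survival(n = 120, p = 200, n_informative = 5,
                         rho = 0.3, seed = 42)
table(sim$data$status)
#>  0  1
#> 49 71

res <- run_semisupervised(sim$data, seed = 42)
res
#> Semi-supervised Cox/AFT result (5 iteration(s))
#> augmented training set: 107 samples ( 36 validated imputations, 13 excluded )
#> Cox selected 10 genes; AFT selected 5 genes
```

Of the 49 censored samples, 36 received a validated survival-time estimate
and now train the models as events; 13 re-estimates fell at or below their
censoring times and were excluded. `tidy()` exposes the per-iteration log
(training-set size, validated/error counts, tuned penalties, support
sizes), and the final fits are ordinary broom-style objects:

```r
selection_precision(res$cox_fit$selected, sim$true_support)
#> # A tibble: 1 × 3
#>   n_correct n_selected precision
#>       <int>      <int>     <dbl>
#> 1         5         10       0.5

augment(res$cox_fit, sim$data)[1:4, c("sample_id", "time", "status",
                                      ".score", ".risk")]
#> # A tibble: 4 × 5
#>   sample_id   time status .score .risk
#>   <chr>      <dbl>  <int>  <dbl> <fct>
#> 1 s0001     0.0602      0  0.569 high
#> 2 s0002     1.16        0 -4.94  low
#> 3 s0003     0.142       0  1.63  high
#> 4 s0004     0.0364      1  1.40  high
```

The final Cox model found all 5 informative genes (plus 5 spurious ones —
precision 0.5), and censored sample s0002, scored low-risk, was imputed
within the low-risk class. `autoplot()` methods draw KM curves, CV curves,
and risk partitions; `plot_risk_km(res$partition, sim$data)` shows the
separated survival curves of the two classes.

A thin command-line wrapper with `simulate` / `fit-cox` / `fit-aft` /
`impute` / `semisup` / `evaluate` / `experiment` subcommands is installed
at `inst/cli/semisurv.R`.

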