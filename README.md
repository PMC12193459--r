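# msktgp

Probabilistic prediction of **hematoma expansion** in hemorrhagic stroke
from routinely collected ICU time series, for biostatisticians and
clinical-ML researchers working with MIMIC-style electronic health
records.

## The model

The hematoma volume of patient *j* is modelled as a non-stationary
Gaussian process with time-varying marginal moments,

&nbsp;&nbsp;&nbsp;&nbsp;V<sub>j</sub>(t) ~ N(M<sub>j</sub>(t), Σ<sub>j</sub>(t)),

and the clinically relevant output is the probability that the volume
crosses the expansion threshold c<sub>j</sub> = max(v<sub>0j</sub> + 12.5,
1.33 v<sub>0j</sub>) ml anywhere in a prediction window of length T hours.
Writing β(t) = P(V(t) ≥ c) for the Gaussian upper-tail probability, the
crossing probability is approximated by a time-inhomogeneous Poisson
hazard integral, discretized as

&nbsp;&nbsp;&nbsp;&nbsp;P<sub>j</sub> = 1 − exp(−Σ<sub>i</sub> β<sub>j</sub>(t<sub>i</sub>) Δt),

with hours as the canonical time unit and a seeded Monte Carlo oracle to
validate the approximation.

The personalized mappings from clinical features to (M<sub>j</sub>,
Σ<sub>j</sub>) are realized by a multi-scale kernel transformer (MSKT): a
frozen random embedding of the standardized feature sequence, a bank of
kernel Gram matrices (linear, polynomial, RBF, Matérn ν = 1.5) over the
embedded time steps, per-step fusion with positional encoding, a
transformer encoder (multi-head self-attention, feed-forward, LayerNorm
with the residual around the feed-forward), and affine mean/variance
heads with a softplus variance link. Training minimizes the Gaussian
negative log-likelihood −Σ log(L + δ) by minibatch gradient descent with
hand-derived analytic gradients (finite-difference-verified), early
stopping on a validation split, and optional subject-level k-fold
cross-validation.

Because the credentialed clinical source data cannot be bundled, the
package includes a seeded synthetic cohort generator that emulates the
structure of such an extract (947 patients, 28 features, 72 h at hourly
sampling, tiered missingness, physiologic outliers, 70/15/15 split) with
known ground-truth volume processes, plus the full preprocessing pipeline
(hourly resampling, one-hot encoding, winsorized outlier handling, tiered
median/KNN imputation — all statistics frozen on the training split) and
the evaluation suite (interval coverage and width, noise-robustness RNH,
confusion-matrix metrics, rank-based AUC).

## Worked example

```r
library(msktgp)

# a small synthetic cohort with known truth
cohort <- simulate_cohort(cohort_spec(n_patients = 200, duration = 36,
                                      horizon = 24, seed = 11,
                                      var_age_coef = 0, var_time_ramp = 0))
split  <- split_cohort(cohort, seed = 2)
pipe   <- fit_pipeline(cohort, split$train)
train  <- as_mskt_data(cohort, pipe, split$train)
test   <- as_mskt_data(cohort, pipe, split$test)

fit <- mskt_fit(train, mskt_config(optimizer = "adam", learning_rate = 3e-4,
                                   batch_size = 8, max_epochs = 40,
                                   patience = 12, seed = 5))
print(fit)
#> Multi-scale kernel transformer non-stationary GP model
#>   140 patients, 36 time steps, 35 features
#>   kernels: linear, polynomial, rbf, matern
#>   encoder: 2 layer(s), d''=64, 4 heads; adam optimizer
#>   trained 19 epoch(s); best validation loss -13.4235 at epoch 7

pe <- predict_expansion_probability(fit, test, horizon = 24)
head(round(pe$probability, 3))
#> [1] 0.005 0.000 0.937 0.070 0.278 1.000
roc_auc(pe$probability, test$labels)
#> [1] 0.7566138
```

`print(fit)` reports the architecture and the best validation epoch (the
loss is the standardized-scale negative log-likelihood, so negative values
are normal); `pe$probability` holds one expansion probability per held-out
patient — the threshold-crossing probability of that patient's predicted
volume distribution over the next 24 h (patient 3 is almost certainly
expanding, patient 2 almost certainly not) — which `roc_auc()` scores
against the ground-truth labels (0.76 here at n = 200; the recovery
experiment at n = 500 reaches about 0.86). See the methods vignette
(`vignettes/mskt-methods.Rmd`) for the model, its assumptions, all
tunable parameters and the design decisions.

The crossing machinery is usable standalone:

```r
g    <- time_grid(horizon = 24, n_points = 240)
proc <- volume_process(g, mean = 20 + 6 * (1 - exp(-g$points / 12)),
                       variance = rep(16, 240))
crossing_probability(proc, expansion_threshold(20))
#> Crossing probability: 0.310624 (cumulative hazard 0.371968, left rule, 240 grid points)
```

A thin command-line wrapper over the same functions lives at
`inst/cli/mskt` (subcommands `simulate`, `train`, `predict`, `evaluate`).

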