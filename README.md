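# claimscast

Temporal persistence and forecasting of patient-level health care
expenditures.

A small share of patients — high-cost, high-need (HCHN) patients, here the
top 10% of per-member-per-month spending — accounts for a disproportionate
share of total medical expenditure. Whether their spending is *persistent*
(and therefore predictable and actionable) or episodic is an empirical
question. `claimscast` provides the full analysis stack to study it on
longitudinal insurance-claims panels: a claims simulator with controllable
temporal structure, persistence statistics, four forecasting model
families implemented from their defining equations, per-prediction
attribution, and a leakage-safe rolling evaluation harness. It is aimed at
health-services and biostatistics researchers who want a tested, fully
reproducible desk-scale environment for expenditure-forecasting methods.

## What is inside

**Objectives.** Claims are aggregated over 1/3/6/12-month periods into
three prediction targets per patient: PMPM (total expenditure divided by
months enrolled), log10(PMPM + 1), and the rank percentile
pctlPMPM ∈ (0, 1] (top spender = 1; HCHN ⇔ pctlPMPM ≥ 0.9). A patient
enters a period only when enrolled strictly more than two-thirds of its
months.

**Persistence.** The two-step temporal-correlation test: rank patients
within two periods, then take the Pearson correlation of the rank
percentiles; plus top-decile retention (the share of one period's top 10%
still in the top 10% later) with follow-up percentile mean ± sd.

**Models.** All four forecasters are implemented in the package:

- *LR* — least squares, with a minimum-norm solution on rank-deficient
  designs;
- *LASSO* — min<sub>θ</sub> (1/n)‖y − Xθ‖² + β‖θ‖₁ by cyclic coordinate
  descent with soft-thresholding, warm starts, an active-set strategy and
  a 10-fold cross-validated penalty;
- *GBM* — second-order gradient boosting: each round grows one tree on the
  gain ½(G<sub>L</sub>²/(H<sub>L</sub>+λ) + G<sub>R</sub>²/(H<sub>R</sub>+λ)
  − G²/(H+λ)), accepted when above γ, with leaf weights −G/(H+λ);
- *RNN* — a dual-attention GRU network: period embeddings
  e<sup>t</sup> = W<sub>T</sub>x<sup>t</sup>, two GRU chains producing an
  elementwise attention β<sup>t</sup> = tanh(W<sub>β</sub>h<sup>t</sup> +
  b<sub>β</sub>) and a scalar period attention α<sup>t</sup>, a context
  c = Σ<sub>t</sub> α<sup>t</sup>β<sup>t</sup> ⊗ e<sup>t</sup> + e<sup>NT</sup>,
  and ŷ = w·c + b, trained by hand-derived backpropagation with ADADELTA
  and dropout 0.5 on embedding and context vectors.

**Attribution.** Every prediction decomposes into additive per-variable
contributions: θ<sub>j</sub>x<sub>j</sub> for the linear models,
gain-proportional redistribution of each tree leaf's weight along its
decision path for the GBM, and the exact rearrangement
x<sub>tk</sub>·α<sup>t</sup>·w·(β<sup>t</sup> ⊗ W<sub>T</sub>[:,k]) for the
network. Contributions + intercept = prediction (exact for linear/trees,
to 1e-6 relative for the network). `bootstrap_stability()` refits on 10
patient-level bootstrap resamples to quantify how stable the
contributions are.

**Evaluation.** Train to predict period t, test on period t+1, never
touching t+1 during training; R², RMSE of rank percentiles, and RMSE
restricted to the actual top decile; averaged over several t.

## Worked example

```r
library(claimscast)

cfg <- generator_config(n_patients = 3000, n_months = 15, seed = 9,
                        rho = 0.9, enroll_gap_prob = 0)
panel <- simulate_population(cfg)
pd <- compute_objectives(aggregate_period(
  panel$claims, panel$enrollment, panel$demographics,
  period_grid(15, 3), panel$maps))

lagged_correlation_table(pd, 1:3)
#>   period_length lag pearson_r n_patients n_pairs
#> 1             3   1 0.3892054       3000       4
#> 2             3   2 0.2882449       3000       3
#> 3             3   3 0.1923842       3000       2

top_decile_persistence(pd, 1, 2)
#>   period_length lag retention_pct mean_followup_pctl sd_followup_pctl n_top
#> 1             3   1       37.2093           73.56213         27.40044   301
```

With a latent severity autocorrelation of 0.9, the quarterly rank
correlation is ≈ 0.39 at lag 1 and decays with lag, and 37% of the top
decile stays in the top decile next quarter (an exchangeable panel would
retain 10%); the ones that drop out still average the 74th percentile.
Fitting and attributing a forecaster:

```r
d <- assemble_design(pd, n_prior = 1, forecast_period = 4,
                     feature_flags = "full", objective = "pctl_pmpm")
fit <- fit_lasso(d, seed = 1)
cs <- linear_contributions(fit, d$x[1, ])
subset(cs$contributions, contribution != 0)
#>           variable period contribution
#> 1 prior1_pctl_pmpm     NA     0.276911
```

For this low-cost patient the cross-validated LASSO attributes the whole
prediction (above the intercept) to the prior-quarter percentile; sicker
patients pick up contributions from their diagnosis-group counts.

The numbered scripts under `analysis/` run the full study: `01_simulate.R`
(writes the claims CSVs), `02_persistence.R` (correlation and retention
tables), `03_baseline_models.R` (prior-expenditure baselines for all three
objectives), `04_experiment_ladder.R` (baseline → +claims features → 1–4
prior periods → period lengths), `05_attribution.R` (bootstrap stability
of contributions). Each writes its tables under `results/`.

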