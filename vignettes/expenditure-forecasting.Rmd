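---
title: "Forecasting health care expenditures: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting health care expenditures: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(claimscast)
```

This vignette is the package's account of its science: the objects and
conventions it fixes, the models it implements and their assumptions, what
the claims simulator does and does not emulate, and the design choices
made where more than one reasonable convention exists. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The setting

Administrative claims record, per patient and month, coded service events
(diagnoses, procedures, drugs) with paid amounts, alongside enrollment
spans and demographics. The scientific questions the package serves are
(1) how persistent patient-level spending is across periods — especially
for high-cost, high-need (HCHN) patients, the top decile of
per-member-per-month (PMPM) spending — and (2) how well next-period
spending can be forecast from prior periods, by which model family, and
with which inputs.

## Objectives and conventions

Claims are aggregated over tiling periods of 1, 3, 6 or 12 months
(half-open month ranges, 0-based). Per patient and period:

* `pmpm` = total paid amount / months enrolled. A patient enters a period
  only when enrolled **strictly more** than two-thirds of its months
  (9 of 12 qualifies, 8 does not); the filter avoids short, volatile
  enrollment fragments.
* `log_pmpm` = log10(pmpm + 1). The +1 offset is a design choice: a large
  fraction of enrolled months have zero spending, and the offset maps them
  to exactly 0 on the log scale rather than dropping them.
* `pctl_pmpm`: the average-rank percentile of PMPM within the period's
  eligible population, **ascending**, so the top spender has percentile 1
  and HCHN means `pctl_pmpm >= 0.9`. Sources describing this statistic
  sometimes phrase the ranking in descending order while displaying HCHN
  patients near the top of the percentile axis; the package standardizes
  on the ascending convention throughout. Ties share the average rank, so
  the point mass of zero-spending patients occupies a single percentile.
  Percentiles are computed within each period independently — a forecast
  target therefore never leaks information across periods.

Grouped code counts use fixed vocabularies of 283 diagnosis groups, 231
procedure groups and 893 drug classes (the cardinalities of the CCS
diagnosis/procedure groupers and the FDA pharmacy-class list). The
full per-period feature block is `[objective value, 283, 231, 893]` =
1408 columns, plus 10 demographics columns (age, sex one-hot, six-way
race/ethnicity one-hot, disabled flag). Feature values are raw event
counts; a presence/absence or log1p transform was considered and left out
because counts preserve dose information the trees and the network can
use.

## The claims simulator

No public claims extract accompanies this package, so the simulator is a
first-class, tested module whose defaults define the study conditions.
Per patient, a latent severity state follows a stationary AR(1),

h_m = mu_i + rho (h_{m-1} - mu_i) + eps_m,  Var(h_m) = sigma^2,

the minimal process exhibiting the temporal persistence the analyses
measure. An enrolled month has zero expenditure with probability
`zero_prob` (independent of severity by default, which keeps the
exchangeable-null analytics exact), otherwise expenditure is lognormal
with log-mean `cost_scale + h_m` — zero-inflated and heavy-tailed, the two
distributional facts everyone agrees on for medical spending. Event
counts per code system are Poisson with rate `event_rate * exp(h_m / 2)`,
so sicker months generate more coded events; codes are drawn uniformly
within uniformly chosen groups. A month's expenditure is split evenly
over its events (only monthly totals are ever analyzed), and a
positive-cost month with no events emits one carrier diagnosis event so
that claim totals conserve expenditures exactly — an invariant the tests
assert.

Chronic cohorts (diabetes, COPD, asthma, hypertension, defined by the
conventional diagnosis-group sets 49/50, 127, 128, 98/99) are Bernoulli
memberships that shift mu_i upward and emit events in *reserved* marker
groups that non-members never touch. The reservation is deliberate: it
makes generator ground truth exactly recoverable from claims, so cohort
selection can be tested as a set equality rather than approximately.

Defaults (`cost_scale = 5.5` log-dollars ≈ $245 median positive month,
`cost_sdlog = 0.7`, `zero_prob = 0.35`, `event_rate = 0.5`/system/month,
`enroll_gap_prob = 0.05`, ages uniform 18–65) describe a Medicaid-like
adult panel at desk scale. No public distributional parameters exist to
calibrate against, so these are conventional choices, fixed once.

What the simulator does **not** emulate: real marginal cost distributions
or code frequencies, pharmacy expenditure streams, payer mechanics,
correlated enrollment spells, or coding practice drift. Tests passing on
synthetic panels therefore demonstrate correctness of the machinery and
the qualitative mechanisms (persistence, feature signal, overfitting
behavior), not calibration to any real program.

The `planted_linear` regime replaces the second half of the window with a
PMPM that is an exactly linear function of the first half's grouped
counts plus Gaussian noise (noise sd a stated fraction of signal sd). The
monthly spend is constant within the planted half, which makes the
planted PMPM invariant to partial enrollment. This regime exists for
parameter-recovery experiments with retrievable ground truth.

## Models

**Least squares** uses the centered normal equations with an
eigendecomposition pseudoinverse; wide designs (p > n) take the dual Gram
route, giving the same minimum-norm solution without densifying the
design. This matters because multi-period designs reach 5,652 columns.

**LASSO** minimizes (1/n)·RSS + beta·||theta||_1 on internally
standardized columns by cyclic coordinate descent (soft-thresholding,
coordinate-change tolerance 1e-7), with warm starts along a decreasing
penalty path and an active-set strategy with KKT screening — the standard
architecture for high-dimensional sparse designs. The 1/n objective
scaling makes the one-predictor solution the textbook soft-threshold
S(⟨x,y⟩/n, beta/2); the all-zero dead zone then starts at
2·max|⟨x_j,y⟩|/n. The penalty is chosen at the minimum of 10-fold
cross-validated error; fold assignment is seeded and recorded.
Standardization statistics come from training data only and are reused on
test data.

**Gradient boosting** is second-order: with squared-error loss the
working derivatives are g_i = yhat_i − y_i, h_i = 1; each round grows one
tree greedily on the regularized gain with leaf weights −G/(H+λ), a split
accepted only when its gain exceeds γ. The base score is the training
mean; equal-gain ties resolve to the lowest feature index, then the
lowest threshold, making fits bit-reproducible. The reference protocol is
1000 trees with a depth/learning-rate grid under 5-fold CV; the desk-scale
experiments use documented smaller settings (25–50 rounds, depth 2–3)
chosen for the problem sizes below.

**The attention network** embeds each period's 1408 inputs to E
dimensions and the statics once; two independent single-layer GRU chains
run oldest→newest (the direction is a design choice; nothing in the
architecture fixes it), one producing an E-vector attention
beta^t = tanh(W_b h^t + b_b), the other a scalar attention
alpha^t = tanh(w_a·g^t + b_a). The scalar head is a plain tanh readout
of the second GRU's state — no softmax normalization across periods is
applied, since the attention weights multiply into an additive context
c = Σ_t alpha^t beta^t ⊗ e^t + e^NT and the prediction is w·c + b.
Because the recurrences only *gate* the inputs, the prediction is exactly
linear in the inputs given the attentions — the property that makes
per-variable attribution an identity rather than an approximation.

Training minimizes mean squared error with hand-derived backpropagation
through both GRU chains (gradients verified against central finite
differences in the test suite) and ADADELTA (decay 0.95, eps 1e-6), with
inverted dropout on embedding and context vectors (reference rate 0.5,
training only). Initialization is uniform scaled by fan-in; the scalar
attention bias starts at 0.5 so the period gate passes signal early in
training rather than starting shut. Inputs are scaled by training-set
standard deviations but **not centered**: centering would smear column
means into every attribution, whereas scale-only normalization keeps the
all-zero input mapping exactly to the intercept. The target is centered
and scaled; the reported intercept absorbs the de-standardization.
Reference embedding size is 128; the desk-scale experiments use E = 16
(and 8 for bootstrap refits), which is ample for the synthetic signal
and keeps single-CPU runtimes in seconds.

## Attribution

Contributions are additive decompositions of single predictions:
theta_j·x_j for linear models; for trees, the reached leaf's shrunken
weight redistributed over the root-to-leaf splitting nodes
proportionally to each node's split gain (equal shares when all path
gains are zero; splitless trees credit the intercept) — this
"weighed by the gain" reading is chosen over per-node weight-delta
schemes because it conserves exactly by construction; for the network,
the exact rearrangement of the forward pass, computed with dropout off.
Bootstrap stability resamples *patients* with replacement (respecting
within-patient dependence), refits with the same procedure and seed
policy, and attributes the same probe patients each time; 10 resamples is
the reference protocol.

## Evaluation protocol

Models are trained to predict period t and tested on period t+1; a
structural audit verifies no training feature derives from period t or
later. Metrics: R², RMSE of rank percentiles, and RMSE restricted to
patients whose *actual* test-period percentile is ≥ 0.9. The actual
(rather than predicted) decile is a design choice: it measures targeting
error on the patients who truly turned out expensive. When the objective
is PMPM or logPMPM, predictions and truths are both ranked within the
test period so percentile errors remain comparable across objectives.
Metrics are averaged over the available t values (mean of per-t metrics;
at least three t's where the grid allows, one for 12-month periods).

## Problem sizes and numerical choices

The packaged experiments run on a single CPU: persistence panels of
3,000–5,000 patients over 15–24 months; an exchangeable null of 50,000
patients for retention calibration; planted-recovery panels of 5,000
patients; and a feature-comparison panel of 12,000 patients. The
feature-comparison size is the one setting where scale is load-bearing:
an unregularized linear model with 1,418 columns needs n well above p
before added features help out-of-sample, and the experiment is designed
to sit on the favorable side of that ratio while the 4-prior-period
variant (5,652 columns > n) deliberately sits on the unfavorable side —
exhibiting the overfitting mechanism that regularized and embedded models
avoid. Coordinate-descent tolerance is 1e-7 on coefficient changes;
degenerate inputs (constant columns, zero-variance targets, empty top
deciles, fewer than 3 patients) raise explicit errors rather than
propagating NaNs.

## Limitations

Synthetic panels only; a single AR(1) latent driver with independent
zero-inflation (real spending has episodic structure, state-dependent
zeros and code-specific cost signatures); uniform code draws within
groups (real code frequencies are Zipf-like); no pharmacy spend stream;
no significance testing of correlations; attribution is local and
per-prediction — no Shapley values or global importances beyond
aggregated path contributions.
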