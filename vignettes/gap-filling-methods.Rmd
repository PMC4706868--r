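---
title: "Neural-network gap filling of ocean-color fields: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural-network gap filling of ocean-color fields: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Satellite ocean-color retrievals of chlorophyll-a concentration (Chl-a,
mg/m³) have persistent spatial and temporal gaps — clouds, swath geometry,
sun glint — while many downstream applications (biogeochemical modelling,
data assimilation, ecological forecasting) need gap-free daily fields.
Chlorophyll variability is, to a large extent, driven by the physical state
of the upper ocean, which *is* observed more completely: sea-surface height
(SSH), sea-surface salinity (SSS), sea-surface temperature (SST) and
upper-ocean temperature/salinity profiles.  `ocgapfill` treats gap filling
as a regression problem: learn the mapping from the physical state (plus
space-time metadata) to Chl-a wherever both are observed, then evaluate the
mapping wherever Chl-a is missing but the physics is available.

## The statistical model

The observed Chl-a at a grid cell and day is modelled as a stochastic
mapping

$$ Y = M(X) + \varepsilon, $$

where $X \in \mathbb{R}^{23}$ collects the predictors, $M$ is an unknown
smooth nonlinear function, and $\varepsilon$ aggregates subgrid-scale
variability and observation noise.  The residual $\varepsilon$ is not a
nuisance to be driven to zero: a well-trained emulator's test error should
*approach* the magnitude of $\varepsilon$ and stop there.  Driving training
error below it means fitting noise.

$M$ is emulated by a multilayer perceptron with a single hidden layer of
$k$ hyperbolic-tangent units and a linear output:

$$ y = a_0 + \sum_{j=1}^{k} a_j \tanh\Big(b_{j0} + \sum_{i=1}^{n} b_{ji}
x_i\Big). $$

The output is deliberately linear and unclipped: negative predictions are
possible in principle and are reported as-is, leaving any clamping to the
user.  Training minimizes the mean squared error
$E = \frac{1}{N}\sum_i (Y_i - \mathrm{NN}(X_i))^2$ on the training set
while monitoring $E$ on a held-out test set; the weights returned are those
of the epoch with minimum test error (early stopping).

### Input encoding

The 23 inputs, in fixed order (see `input_names()`):

| # | input | encoding |
|---|-------|----------|
| 1 | year | raw, standardized like any input |
| 2–3 | day of year | $\sin(2\pi t/D)$, $\cos(2\pi t/D)$ |
| 4–5 | longitude | $\sin(\lambda)$, $\cos(\lambda)$ |
| 6 | latitude | $\sin(\phi)$ |
| 7–9 | SSH (m), SSS (g/kg), SST (°C) | raw |
| 10–16 | salinity profile, 7 levels (g/kg) | raw |
| 17–23 | temperature profile, 7 levels (°C) | raw |

Cyclic quantities get paired sine/cosine components so that day 366 is
close to day 1 and 180°E to 180°W.  Latitude is encoded with its sine only
— no cosine partner — reproducing the operational input listing faithfully
even though it is asymmetric with the other two encodings.  The day
denominator $D$ is configurable because the source conventions disagree
(365 in the formula-level description, 366 in the operational table); the
package defaults to `day_denominator = 366` and exposes the switch
prominently.  Profile levels are positional (level 1 shallow to level 7 at
the bottom of the upper layer); no depth values enter the encoding.

Inputs and target are z-scored with constants fitted on the training set
(`fit_standardizer()`).  Whether the original system standardized its
inputs is unstated; z-scoring is the conventional choice for tanh networks
and is treated here as part of the model definition.  Constant columns
(e.g. `year` in a single-year dataset) get scale 1 and map to zero, with a
warning, rather than poisoning the optimization with a division by zero.
Predictions are mapped back to mg/m³.

### Training: optimizer and determinism

No optimizer is prescribed by the method itself; the contract is only on
the achieved test error.  The package uses mini-batch Adam (default
learning rate 0.01, batch size 1024) with seeded uniform
$\pm 1/\sqrt{\text{fan-in}+1}$ initialization and seeded shuffling, which
makes every training run bit-reproducible from `(data, architecture,
options)`.  Early stopping uses `patience = 50` epochs by default; an
optional `target_error` bound (the $\varepsilon^2$ criterion) can stop
training as soon as the test error reaches a prescribed noise level, but it
is off by default because $\varepsilon$ is generally unknown a priori.
The epoch-0 (initial) weights participate in best-epoch selection, so the
returned network is never worse on the test set than the initial one; a
non-finite loss aborts with a diagnostic rather than returning garbage.

### Ensembles and the averaged Jacobian

A single network is a point estimate of a stochastic mapping.  The package
trains an ensemble (default six members, architecture 23:30:1) that share
training data and differ only in their initialization seed, so members
settle in different local minima; the ensemble mean is the product
prediction and the member spread (sample standard deviation) a cheap
stability indicator.  The mean prediction's MSE is algebraically bounded by
the average member MSE (Jensen's inequality), which the test suite asserts
to 1e-12.

Input sensitivity uses the network Jacobian.  Differentiating the model
gives

$$ \frac{\partial y}{\partial x_s} = \sum_{j=1}^{k} a_j (1 - t_j^2)
b_{js}, \qquad t_j = \tanh\Big(b_{j0} + \sum_i b_{ji} x_i\Big). $$

(One published rendering of this derivative swaps the roles of the $a$ and
$b$ weights; the package follows the calculus, and verifies the
implementation against central finite differences to 1e-6 as an acceptance
property.)  Because differentiating a statistical fit is ill-posed, the
reported sensitivity is the ensemble- and record-averaged absolute
Jacobian: $|\partial y / \partial x_i|$ averaged over an evaluation set
(default: the test records) and over members, with the induced descending
ranking (`ensemble_jacobian()`).  Sensitivities are computed in
standardized input space by default so that °C, g/kg and metres are
comparable; `physical_units = TRUE` rescales if derivatives in mg/m³ per
physical unit are wanted.  Where exactly the original analysis evaluated
its Jacobian is unstated; averaging over the held-out set is the most
defensible reading of a "mean Jacobian".

### Uncertainty decomposition

The prediction RMSE decomposes as
$\mathrm{RMSE} = \varepsilon_{\mathrm{app}} + \varepsilon$: the
approximation capability of the network machinery itself plus the
irreducible data uncertainty.  $\varepsilon_{\mathrm{app}}$ is estimated by
training a 1:30:1 network whose single input *is* the target value — an
identity-mapping emulation (`estimate_epsilon_app()`).  Its held-out RMSE
is pure approximation error.  On $10^5$ chlorophyll-like values this is of
order $10^{-4}$–$10^{-3}$ mg/m³, a small fraction of typical total RMSE,
so essentially all of the prediction error reflects $\varepsilon$ — the
justification for not pursuing more elaborate regressors.

## Data handling and evaluation conventions

* **Record assembly** (`assemble_records()`): one record per (ocean cell,
  day) with *all* 17 physical predictors valid, in canonical order
  time-major → latitude → longitude.  Records with complete predictors but
  missing Chl-a are the gaps to be filled.  The completeness rule is
  strict: the source pipeline composites inputs to daily coverage and is
  silent on residual missingness, so partial predictor vectors are
  excluded from training and flagged `unfillable` in prediction.
* **Splitting** (`alternating_split()`): every second record of the
  canonical stream goes to training, the rest to test.  Whether the
  original alternation ran over space, time, or the flattened stream is
  ambiguous; the flattened stream is the most literal reading and is what
  is implemented.  A by-year mode supports the generalization experiments.
* **Metrics** (`compute_metrics()`): bias is mean(observed − predicted) —
  the "observation minus network" convention — RMSE likewise on
  observed − predicted, and Pearson correlation; correlation on degenerate
  (zero-variance) inputs is reported as `NA` rather than an arbitrary 1.
* **Threshold filtering** (`filter_threshold()`): concentrations above
  1.0 mg/m³ (a fraction of a percent of open-ocean data) are too sparse to
  train on and dominate error statistics; diagnostics are reported with
  and without records above the threshold.  The boundary value 1.0 is
  kept.
* **Binned statistics** (`binned_stats()`): bins on *observed* Chl-a,
  half-open `[lo, hi)` with the last bin closed, default 20 equal bins on
  [0, 2] mg/m³ (no bin width is prescribed anywhere; the edges are always
  user-settable).  Out-of-range records go to an explicit overflow row so
  bin counts always sum to N, and the count-weighted bin MSEs reproduce
  the global MSE exactly.  Fractions are reported raw (any display scaling
  is a plotting concern, not data).
* **Global means** (`daily_metric_series()`): unweighted over valid grid
  cells, matching the plain reading of a "global mean"; a cos(latitude)
  area weighting is available but off by default.
* **Gap filling** (`fill_gaps()`): observed values are never overwritten —
  network values only fill masked cells — and each ocean cell-day is
  labelled `observed`, `filled` or `unfillable`, so the three counts
  always sum to the ocean-cell count.

## The synthetic ocean

Real VIIRS/Argo/Aquarius archives are outside this package's scope, so all
validation runs on a synthetic-ocean generator (`synth_config()`,
`generate_dataset()`) that reproduces the *statistical structure* the
method relies on, with a known truth:

* smooth physical fields on a regular grid (default 18 × 36 cells at 10°,
  two 365-day years): an equator-warm SST with hemisphere-antisymmetric
  seasonal cycle, SSS with latitudinal structure, SSH within ±1 m, and
  seven-level profiles attenuating toward depth, plus deterministic
  pseudo-continents (~20% land);
* seeded smooth anomaly fields (a few spatial harmonics with mostly
  annual-periodic temporal factors) that give each variable variance that
  cannot be read off any other input.  The SST anomaly amplitude is
  deliberately generous relative to the real ocean: the sensitivity-
  recovery experiment needs the dominant predictor's signal to be
  separable from the metadata inputs that co-vary with it, and subsurface
  temperature tracks the climatological rather than instantaneous surface
  signal for the same reason;
* a documented closed-form mapping (`true_chla_mapping()`) from SST, SSS
  and one subsurface salinity level to noise-free Chl-a through a log
  link, with configurable per-input weights so the true sensitivity
  ordering is known.  Its two constants are frozen from a one-off
  calibration of the default configuration: median 0.35 mg/m³ and roughly
  0.2–0.3% of open-ocean values above 1.0 mg/m³, i.e. a right-skewed
  distribution with well over 99% of values at or below 1 mg/m³;
* additive Gaussian noise (default σ = 0.1 mg/m³), clipped below at
  0.001 mg/m³ to keep concentrations positive — with the bulk of the
  distribution sitting well above the clip, the clip does not materially
  distort the residuals.  A heteroscedastic option scales σ with the true
  concentration, emulating noisier high-chlorophyll (coastal) retrievals;
* uniform random gaps at a configurable fraction (default 20%).  Real
  cloud masks are spatially correlated; uniform gaps are sufficient for
  exercising the fill logic and are not claimed to be more;
* an interannual `drift` control under which the physical→Chl-a relation
  itself evolves (the SST climatology shifts by `drift` °C per year, the
  mapping's SST weight grows and its salinity weights shrink year over
  year).  This is what makes the generalization experiment informative: a
  model trained on one year has a constant year input and cannot learn
  interannual evolution, while a two-year model can.

What passing these tests shows — and does not.  Success on the synthetic
ocean demonstrates that the machinery is correct: the optimizer reaches
the noise floor instead of fitting noise, the ensemble average behaves as
theory says, the averaged Jacobian recovers a known dominant input, and
two training years beat one under drift.  It does not demonstrate skill on
real retrievals, whose noise is non-Gaussian, whose gaps are correlated
with the signal (clouds), and whose physical-biological coupling is far
richer than a three-variable log link.

## Validation experiments and problem sizes

The package's validation experiments (mirrored by `tests/testthat/` and
recomputed from scratch by `scripts/acceptance.R`) use these study
conditions, stated here as the package's own choices:

* identity-mapping ε_app: 1:30:1 network on 10⁵ chlorophyll-like scalars,
  alternating split; acceptance bound 0.002 mg/m³;
* noise floor: default synthetic dataset (18 × 36, 730 days,
  σ = 0.1 mg/m³, 20% gaps), 3-member ensemble with k = 10; test RMSE must
  land in [0.9σ, 1.3σ] with correlation ≥ 0.9 against the noise-free
  truth;
* sensitivity recovery: ten repetitions on 12 × 24 × 365 datasets
  (different seeds), 2-member ensembles with k = 8 capped at 2 × 10⁴
  training records; the configured dominant input must rank first in at
  least nine;
* hidden-size sweep: k ∈ {1, 2, 4, 8, 12} on a low-noise
  (σ = 0.02 mg/m³) dataset, where the selected k must beat k = 1 by at
  least 20% test RMSE; with noise at its default level the curve's
  plateau sits at the noise floor and compresses the contrast, which is
  why the sweep condition lowers σ;
* generalization: three years at drift 2, one- vs two-year training with
  the third year held out for validation.

Hidden sizes and record caps in these experiments are smaller than the
23:30:1 production default; they are chosen so each experiment still
exhibits the property it probes while a full validation run completes in
minutes on one CPU.

## Known limitations

* The gridded I/O dialect is long-format CSV; no NetCDF reader/writer is
  bundled.
* The generator makes no attempt at ocean dynamics, bio-optics, realistic
  cloud geometry or realistic Argo sampling; it is a test harness, not a
  simulator.
* Input-subset selection (which metadata and how many profile levels to
  include) is supported only implicitly via encoding masks a user can
  apply before training; no automated search is provided.
* Ensemble members differ only by initialization (no bagging or weighted
  averaging), matching the method being implemented.
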