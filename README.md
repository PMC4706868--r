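# ocgapfill

Neural-network ensemble gap filling for satellite ocean-color
(chlorophyll-a) fields.

Satellite chlorophyll-a retrievals have persistent gaps — clouds, swath
geometry, glint — while the physical state of the upper ocean (sea-surface
height, salinity, temperature, and upper-ocean T/S profiles) is observed
far more completely. Because chlorophyll variability is largely driven by
that physical background, the missing biology can be estimated from the
observed physics. `ocgapfill` is for researchers building gap-free daily
chlorophyll products (for biogeochemical modelling, assimilation, or
time-series work) and for anyone who wants a compact, fully reproducible
implementation of the ensemble-MLP gap-filling technique to experiment
with.

## The method

Observed chlorophyll is modelled as a stochastic mapping
*Y* = *M*(*X*) + *ε*, where *X* ∈ ℝ²³ collects six space-time metadata
components (year; sin/cos of day-of-year; sin/cos of longitude; sin of
latitude) and seventeen physical predictors (SSH, SSS, SST, and seven-level
salinity and temperature profiles), and *ε* aggregates subgrid variability
and observation noise. *M* is emulated by a single-hidden-layer tanh
perceptron with linear output,

    y = a₀ + Σⱼ aⱼ tanh(bⱼ₀ + Σᵢ bⱼᵢ xᵢ),   j = 1..k,

trained by minimizing the mean squared error E = (1/N) Σ (Yᵢ − NN(Xᵢ))²
with early stopping on a held-out test set (every second record of the
canonical record stream). An ensemble of such networks — identical
architecture and data, different initialization seeds — provides the
product prediction (ensemble mean), and the ensemble- and record-averaged
absolute Jacobian |∂y/∂xᵢ| gives a stable input-sensitivity ranking.
Training error is expected to approach the data uncertainty *ε* and stop
there; the approximation-error component of the RMSE is estimated
separately by training a 1:k:1 network to emulate the identity mapping.

Everything is validated against a bundled synthetic-ocean generator with a
known closed-form physical→chlorophyll mapping, known noise level, known
dominant predictor, and controllable gaps and interannual drift.

## Worked example

```r
library(ocgapfill)

# two synthetic years on a 12 x 24 grid, sigma = 0.1 mg/m3, 20% gaps
cfg   <- synth_config(nlat = 12, nlon = 24, n_days = 730, seed = 42)
ocean <- generate_dataset(cfg)
ocean
#> ocean_grid: 12 x 24 cells (228 ocean), 730 days (2012-2013)
#>   chla present; 20.0% of ocean cell-days missing

fit <- gapfill_train(ocean, arch = mlp_architecture(23, 10, 1),
                     n_members = 3, base_seed = 1,
                     opts = training_options(max_epochs = 60, patience = 15,
                                             batch_size = 2048))
fit
#> gapfill_fit: 3 member(s); 133230 labelled records (66615 train / 66615 test),
#> 33210 gaps

pred <- ensemble_predict(fit$ensemble, fit$test$x)
compute_metrics(pred$mean, fit$test$y)
#>           bias      rmse       cc     n
#> 1 4.350637e-05 0.1001175 0.895107 66615
```

The test RMSE (0.100 mg/m³) sits on the injected noise floor
(σ = 0.1 mg/m³) — the network has learned the mapping down to the data
uncertainty, and the near-zero bias says it is unbiased about it. Filling
the gaps and ranking the inputs:

```r
filled <- fill_gaps(fit, ocean)
table(filled$provenance)
#>   filled observed
#>    33210   133230

sens <- ensemble_jacobian(fit$ensemble, fit$test$x)
head(sens[order(sens$rank), ], 5)
#>    input    name mean_abs_jacobian rank
#> 9      9     sst        0.54128954    1
#> 6      6 lat_sin        0.17955905    2
#> 13    13   sal_4        0.13630469    3
#> 8      8     sss        0.13567727    4
#> 21    21  temp_5        0.08151465    5
```

All 33,210 gap cell-days with complete predictors received an
ensemble-mean value (observed cells are never overwritten), and the
sensitivity ranking recovers the generator's ground truth: SST carries the
largest weight in the synthetic mapping, with surface and subsurface
salinity among the runners-up.

A command-line wrapper with `simulate`, `train`, `fill`, `evaluate`,
`sensitivity` and `sweep-k` subcommands is installed at
`inst/cli/ocgapfill.R`; gridded datasets travel as a long-format CSV
dialect (`write_grid_csv()` / `read_grid_csv()`) and trained ensembles as
JSON model directories (`write_ensemble()` / `read_ensemble()`).

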