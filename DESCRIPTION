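Package: ocgapfill
Title: Neural-Network Ensemble Gap Filling for Satellite Ocean-Color Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fills spatial and temporal gaps in gridded satellite ocean-color
    (chlorophyll-a) fields using an ensemble of single-hidden-layer tanh
    perceptrons trained on physically related surface and upper-ocean
    predictors (sea-surface height, salinity and temperature plus seven-level
    upper-ocean salinity and temperature profiles) together with cyclically
    encoded space-time metadata. Provides from-scratch network training with
    early stopping, analytic and ensemble-averaged Jacobians for input
    sensitivity ranking, uncertainty decomposition via an identity-mapping
    network, bias/RMSE/correlation diagnostics with threshold filtering and
    binned statistics, an end-to-end gap-filling pipeline over gridded daily
    fields, and a synthetic-ocean generator for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
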