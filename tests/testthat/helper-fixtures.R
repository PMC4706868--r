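# shared fixtures, built once per test run and cached

quick_opts <- function(...) {
  training_options(max_epochs = 30L, patience = 10L, batch_size = 512L, ...)
}

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small synthetic dataset exercising gaps, land and seasonality
tiny_grid <- function() {
  fixture("tiny_grid", function() {
    generate_dataset(synth_config(nlat = 8, nlon = 12, n_days = 60,
                                  seed = 7, gap_fraction = 0.15))
  })
}

# full-size gap-free dataset for distribution checks
default_grid_nogap <- function() {
  fixture("default_grid_nogap", function() {
    generate_dataset(synth_config(seed = 1, gap_fraction = 0))
  })
}

# a trained two-member ensemble on the tiny dataset
tiny_fit <- function() {
  fixture("tiny_fit", function() {
    suppressWarnings(
      gapfill_train(tiny_grid(), arch = mlp_architecture(23, 4, 1),
                    n_members = 2L, base_seed = 11L, opts = quick_opts(),
                    max_train_records = 3000L))
  })
}

# hand-buildable fully valid grid for pipeline unit tests
mini_grid <- function(nlat = 2L, nlon = 2L, nt = 2L, chla = NULL,
                      ocean = matrix(TRUE, nlat, nlon)) {
  d3 <- c(nlat, nlon, nt)
  base <- array(seq_len(prod(d3)) / prod(d3), d3)
  if (is.null(chla)) chla <- 0.2 + 0.1 * base
  ocean_grid(lat = seq(-45, 45, length.out = nlat),
             lon = seq(-90, 90, length.out = nlon),
             years = rep(2012L, nt), day_of_year = seq_len(nt),
             ocean = ocean,
             ssh = 0.1 * base, sss = 35 + base, sst = 20 + base,
             sal = array(35, c(nlat, nlon, 7, nt)),
             temp = array(15, c(nlat, nlon, 7, nt)),
             chla = chla)
}

# fixed-weight constant-output network: always returns `value`
constant_net <- function(arch, value) {
  a <- matrix(0, arch$n_outputs, arch$n_hidden + 1L)
  a[, 1] <- value
  b <- matrix(0, arch$n_hidden, arch$n_inputs + 1L)
  ocgapfill:::new_mlp_params(arch, a, b)
}
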