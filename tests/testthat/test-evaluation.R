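test_that("metrics follow the obs-minus-pred convention", {
  expect_equal(compute_metrics(c(0, 1), c(1, 2)),
               data.frame(bias = 1, rmse = 1, cc = 1, n = 2L))
  m <- compute_metrics(1:4, 1:4)
  expect_equal(m$bias, 0); expect_equal(m$rmse, 0); expect_equal(m$cc, 1)
  # constant vectors: correlation undefined
  expect_true(is.na(compute_metrics(rep(1, 3), rep(1, 3))$cc))
  obs <- c(0.1, 0.5, 0.9)
  expect_equal(compute_metrics(-obs, obs)$cc, -1)
  expect_error(compute_metrics(1:3, 1:4), "lengths differ")
  # rmse >= |bias| always
  set.seed(1)
  for (i in 1:20) {
    m <- compute_metrics(rnorm(50), rnorm(50))
    expect_gte(m$rmse, abs(m$bias))
  }
})

test_that("metrics are translation-consistent and cc affine-invariant", {
  set.seed(2)
  pred <- rnorm(100); obs <- pred + rnorm(100, sd = 0.3)
  m0 <- compute_metrics(pred, obs)
  m1 <- compute_metrics(pred + 5, obs + 5)
  expect_equal(m0$bias, m1$bias, tolerance = 1e-12)
  expect_equal(m0$rmse, m1$rmse, tolerance = 1e-12)
  m2 <- compute_metrics(3 * pred + 2, obs)
  expect_equal(m0$cc, m2$cc, tolerance = 1e-12)
})

test_that("threshold filtering keeps the boundary and drops the tail", {
  expect_equal(filter_threshold(c(0.5, 1.0, 1.5)), c(TRUE, TRUE, FALSE))
  expect_equal(filter_threshold(c(0.1, 0.2)), c(TRUE, TRUE))
  # the synthetic ocean's tail above 1 mg/m3 is a fraction of a percent
  g <- default_grid_nogap()
  obs <- g$chla[!is.na(g$chla)]
  removed <- 1 - mean(filter_threshold(obs))
  expect_gt(removed, 0.0005)
  expect_lt(removed, 0.03)
  # encoded-records method subsets consistently
  fit <- tiny_fit()
  kept <- filter_threshold(fit$test, max_chla = 0.4)
  expect_true(all(kept$y <= 0.4))
  expect_identical(nrow(kept$x), length(kept$y))
})

test_that("binned statistics partition the data and match hand values", {
  pred <- c(0.1, 0.3, 0.6, 0.9)
  obs <- c(0.2, 0.4, 0.5, 0.7)
  b <- binned_stats(pred, obs, edges = c(0, 0.45, 0.9))
  expect_equal(b$count, c(2L, 2L))
  expect_equal(b$bias, c(mean(c(0.1, 0.1)), mean(c(-0.1, -0.2))))
  expect_equal(sum(b$count), 4L)
  expect_equal(sum(b$fraction), 1, tolerance = 1e-12)

  # single bin equals global metrics
  g1 <- binned_stats(pred, obs, edges = c(0, 1))
  m <- compute_metrics(pred, obs)
  expect_equal(g1$bias, m$bias)
  expect_equal(g1$rmse, m$rmse)

  # constant residual within a bin -> sd 0
  bc <- binned_stats(c(0.1, 0.2), c(0.3, 0.4), edges = c(0, 1))
  expect_equal(bc$resid_sd, 0)

  # records outside the edges land in the overflow row
  bo <- binned_stats(c(0, 0), c(0.5, 3), edges = c(0, 1))
  expect_equal(sum(bo$count), 2L)
  expect_true(any(is.na(bo$bin)))
})

test_that("count-weighted per-bin MSE reproduces the global MSE", {
  set.seed(3)
  obs <- rlnorm(500, -1.5, 0.5)
  pred <- obs + rnorm(500, sd = 0.1)
  b <- binned_stats(pred, obs, edges = seq(0, 2, length.out = 11))
  keep <- b$count > 0
  mse_binned <- sum(b$count[keep] * b$rmse[keep]^2) / sum(b$count)
  expect_equal(mse_binned, mean((obs - pred)^2), tolerance = 1e-10)
})

test_that("daily series and bias maps respond to residual structure", {
  g <- mini_grid(nlat = 2, nlon = 2, nt = 3)
  g$chla_pred <- g$chla            # perfect predictions
  s <- daily_metric_series(g)
  expect_equal(nrow(s), 3L)
  expect_true(all(s$rmse == 0))
  expect_true(all(is.na(s$cc)) || all(abs(s$cc - 1) < 1e-12))
  expect_true(all(spatial_bias_map(g) == 0))

  # constant residual r: RMSE = |r|, bias map = r in every cell
  g2 <- g; g2$chla_pred <- g$chla - 0.1
  s2 <- daily_metric_series(g2)
  expect_equal(s2$rmse, rep(0.1, 3), tolerance = 1e-12)
  expect_equal(unname(spatial_bias_map(g2)), matrix(0.1, 2, 2),
               tolerance = 1e-12)

  # filtered and unfiltered series differ only where obs exceed threshold
  g3 <- g2
  g3$chla[1, 1, 2] <- 1.5
  sf <- daily_metric_series(g3, apply_filter = TRUE)
  su <- daily_metric_series(g3, apply_filter = FALSE)
  expect_equal(sf$n[c(1, 3)], su$n[c(1, 3)])
  expect_lt(sf$n[2], su$n[2])

  # land cells stay masked in the bias map
  oc <- matrix(TRUE, 2, 2); oc[2, 2] <- FALSE
  g4 <- mini_grid(nlat = 2, nlon = 2, nt = 3, ocean = oc)
  g4$chla[2, 2, ] <- NA
  g4$chla_pred <- g4$chla
  expect_true(is.na(spatial_bias_map(g4)[2, 2]))

  # a day with no valid points is flagged, not dropped
  g5 <- g2; g5$chla[, , 2] <- NA
  s5 <- daily_metric_series(g5)
  expect_equal(s5$n[2], 0L)
  expect_true(is.na(s5$rmse[2]))
})

test_that("hidden-size sweep selects the smallest adequate network", {
  set.seed(4)
  x <- matrix(runif(3000, -2, 2), ncol = 1)
  y <- sin(2 * x) + rnorm(3000, sd = 0.05)
  tr <- mlp_records(x[1:1500, , drop = FALSE], y[1:1500])
  te <- mlp_records(x[1501:3000, , drop = FALSE], y[1501:3000])
  sw <- hidden_size_sweep(tr, te, k_values = c(1, 5, 20), seed = 2,
                          opts = training_options(max_epochs = 300,
                                                  patience = 80))
  expect_lt(sw$test_rmse[sw$k == 5], sw$test_rmse[sw$k == 1])
  expect_lt(abs(sw$test_rmse[sw$k == 20] - sw$test_rmse[sw$k == 5]), 0.05)
  expect_true(attr(sw, "best_k") %in% c(5, 20))
  # single candidate returns that candidate
  sw1 <- hidden_size_sweep(tr, te, k_values = 3, seed = 2,
                           opts = quick_opts())
  expect_equal(attr(sw1, "best_k"), 3L)
})

test_that("identity-mapping network yields a small eps_app and a sane
           decomposition", {
  set.seed(5)
  vals <- runif(20000)
  fit <- estimate_epsilon_app(vals, k = 30, seed = 1,
                              opts = training_options(max_epochs = 150,
                                                      patience = 50,
                                                      learning_rate = 0.005,
                                                      batch_size = 512))
  expect_lte(fit$eps_app, 0.002)
  expect_gte(fit$cc, 0.999)
  dec <- uncertainty_decomposition(0.1, fit)
  expect_gte(dec$epsilon, 0)
  expect_lte(dec$epsilon, dec$rmse)
  expect_error(estimate_epsilon_app(rep(0.3, 2000)), "constant")
  expect_error(estimate_epsilon_app(runif(10)), "at least 1000")
})
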