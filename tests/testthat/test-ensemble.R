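make_xy <- function(n, seed, f) {
  set.seed(seed)
  x <- matrix(rnorm(n * 3), ncol = 3)
  mlp_records(x, f(x) + rnorm(n, sd = 0.05))
}

test_that("single-member ensembles reduce to the single network", {
  tr <- make_xy(400, 1, function(x) 0.5 * x[, 1])
  te <- make_xy(400, 2, function(x) 0.5 * x[, 1])
  arch <- mlp_architecture(3, 4, 1)
  e <- train_ensemble(tr, te, arch, n_members = 1, base_seed = 5,
                      opts = quick_opts())
  single <- train_mlp(tr, te, arch, quick_opts(seed = 5))
  expect_identical(e$members[[1]], single$params)
  pr <- ensemble_predict(e, te$x, standardized = TRUE)
  expect_equal(pr$mean, drop(mlp_forward(single$params, te$x)))
  expect_true(all(pr$spread == 0))
})

test_that("members differ and predictions average with sample spread", {
  arch <- mlp_architecture(2, 3, 1)
  m1 <- constant_net(arch, 0.2)
  m2 <- constant_net(arch, 0.4)
  e <- ocgapfill:::new_ensemble(list(m1, m2), list(NULL, NULL), arch,
                                seeds = c(1L, 2L))
  pr <- ensemble_predict(e, matrix(c(1, 2), ncol = 2), standardized = TRUE)
  expect_equal(pr$mean, 0.3)
  expect_equal(pr$spread, sd(c(0.2, 0.4)))  # sample (n-1) convention

  tr <- make_xy(300, 3, function(x) tanh(x[, 2]))
  te <- make_xy(300, 4, function(x) tanh(x[, 2]))
  e2 <- train_ensemble(tr, te, mlp_architecture(3, 3, 1), n_members = 3,
                       base_seed = 1, opts = quick_opts())
  expect_false(identical(e2$members[[1]]$hidden_weights,
                         e2$members[[2]]$hidden_weights))
  expect_identical(e2$seeds, 1:3)
})

test_that("ensemble-mean MSE never exceeds the mean member MSE (Jensen)", {
  fit <- tiny_fit()
  e <- fit$ensemble
  s <- e$standardizer
  xs <- apply_standardizer(s, fit$test$x)
  ys <- standardize_y(s, fit$test$y)
  P <- vapply(e$members, function(p) drop(mlp_forward(p, xs)),
              numeric(nrow(xs)))
  mse_members <- colMeans((P - ys)^2)
  mse_mean <- mean((rowMeans(P) - ys)^2)
  expect_lte(mse_mean, mean(mse_members) + 1e-12)
})

test_that("ensemble-averaged Jacobian ranks a constructed dominant input", {
  # y = tanh(3 * x9) + 0.1 * x8 + noise over 23 standardized inputs
  set.seed(6)
  n <- 4000
  x <- matrix(rnorm(n * 23), ncol = 23)
  y <- tanh(3 * x[, 9]) + 0.1 * x[, 8] + rnorm(n, sd = 0.05)
  tr <- mlp_records(x[1:2000, ], y[1:2000])
  te <- mlp_records(x[2001:4000, ], y[2001:4000])
  e <- train_ensemble(tr, te, mlp_architecture(23, 6, 1), n_members = 2,
                      base_seed = 3, opts = quick_opts())
  sens <- ensemble_jacobian(e, te$x)
  expect_identical(sens$input[sens$rank == 1], 9L)
  expect_true(all(sens$mean_abs_jacobian >= 0))
  expect_setequal(sens$rank, 1:23)

  # constant ensemble -> all sensitivities zero
  arch <- mlp_architecture(3, 2, 1)
  ec <- ocgapfill:::new_ensemble(list(constant_net(arch, 1)), list(NULL),
                                 arch, seeds = 1L)
  sc <- ensemble_jacobian(ec, matrix(rnorm(30), ncol = 3))
  expect_true(all(sc$mean_abs_jacobian == 0))

  # single member: report equals that member's mean |J|
  p <- init_weights(arch, 8)
  e1 <- ocgapfill:::new_ensemble(list(p), list(NULL), arch, seeds = 9L)
  xe <- matrix(rnorm(60), ncol = 3)
  s1 <- ensemble_jacobian(e1, xe)
  manual <- rowMeans(vapply(seq_len(nrow(xe)),
                            function(i) abs(drop(mlp_jacobian(p, xe[i, ]))),
                            numeric(3)))
  expect_equal(s1$mean_abs_jacobian, manual, tolerance = 1e-12)
})

test_that("averaged |Jacobian| is stable across disjoint evaluation halves", {
  fit <- tiny_fit()
  xe <- fit$test$x
  half <- seq_len(nrow(xe)) %% 2 == 0
  s1 <- ensemble_jacobian(fit$ensemble, xe[half, ])
  s2 <- ensemble_jacobian(fit$ensemble, xe[!half, ])
  expect_gte(cor(s1$mean_abs_jacobian, s2$mean_abs_jacobian), 0.9)
})

test_that("ensemble serialization round-trips through a model directory", {
  fit <- tiny_fit()
  d <- tempfile()
  write_ensemble(fit$ensemble, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_ensemble(d)
  expect_equal(back$members[[1]]$output_weights,
               fit$ensemble$members[[1]]$output_weights)
  expect_identical(back$seeds, fit$ensemble$seeds)
  x <- fit$test$x[1:5, ]
  expect_equal(ensemble_predict(back, x)$mean,
               ensemble_predict(fit$ensemble, x)$mean)
  f <- tempfile(fileext = ".csv")
  write_sensitivity_csv(ensemble_jacobian(back, x), f)
  expect_identical(nrow(utils::read.csv(f)), 23L)
})
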