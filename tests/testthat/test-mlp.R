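test_that("weight initialization is deterministic, seed-sensitive and shaped", {
  arch <- mlp_architecture(23, 30, 1)
  p1 <- init_weights(arch, seed = 1)
  p2 <- init_weights(arch, seed = 1)
  p3 <- init_weights(arch, seed = 2)
  expect_identical(p1, p2)
  expect_false(identical(p1$hidden_weights, p3$hidden_weights))

  p <- init_weights(mlp_architecture(1, 1, 1), seed = 0)
  expect_identical(dim(p$output_weights), c(1L, 2L))
  expect_identical(dim(p$hidden_weights), c(1L, 2L))
})

test_that("forward pass evaluates the tanh perceptron exactly", {
  arch111 <- mlp_architecture(1, 1, 1)
  # all weights zero -> output zero
  expect_equal(mlp_forward(constant_net(mlp_architecture(3, 4, 1), 0),
                           c(1, -2, 3)), 0)
  # dead hidden unit: b = 0 so tanh(0) = 0 regardless of input
  dead <- ocgapfill:::new_mlp_params(arch111, matrix(c(0, 2), 1),
                                     matrix(c(0, 0), 1))
  expect_equal(mlp_forward(dead, 5), 0)
  # unit network: y = tanh(x)
  unit <- ocgapfill:::new_mlp_params(arch111, matrix(c(0, 1), 1),
                                     matrix(c(0, 1), 1))
  expect_equal(mlp_forward(unit, 1), tanh(1), tolerance = 1e-12)
  # matrix input agrees with row-wise evaluation
  p <- init_weights(mlp_architecture(4, 3, 2), 5)
  X <- matrix(rnorm(20), ncol = 4)
  Y <- mlp_forward(p, X)
  expect_equal(Y[3, ], mlp_forward(p, X[3, ]))
  # dimension mismatch is an error
  expect_error(mlp_forward(p, c(1, 2)), "expects")
})

test_that("output is bounded by the sum of absolute output weights", {
  for (seed in 1:5) {
    p <- init_weights(mlp_architecture(6, 9, 1), seed)
    bound <- sum(abs(p$output_weights[, -1]))
    x <- matrix(rnorm(300, sd = 10), ncol = 6)
    y <- mlp_forward(p, x)
    expect_true(all(abs(y - p$output_weights[1, 1]) <= bound + 1e-12))
  }
})

test_that("analytic Jacobian matches central finite differences", {
  # zero output weights -> constant network, zero Jacobian
  p0 <- constant_net(mlp_architecture(3, 2, 1), 7)
  expect_equal(as.vector(mlp_jacobian(p0, c(1, 2, 3))), c(0, 0, 0))
  # unit slope of tanh at the origin
  unit <- ocgapfill:::new_mlp_params(mlp_architecture(1, 1, 1),
                                     matrix(c(0, 1), 1), matrix(c(0, 1), 1))
  expect_equal(drop(mlp_jacobian(unit, 0)), 1, tolerance = 1e-12)

  # property: 100 random (params, x) pairs across architectures
  archs <- list(mlp_architecture(1, 1, 1), mlp_architecture(3, 2, 1),
                mlp_architecture(23, 30, 1))
  set.seed(42)
  for (i in 1:100) {
    arch <- archs[[(i %% 3) + 1]]
    p <- init_weights(arch, i)
    x <- rnorm(arch$n_inputs)
    J <- mlp_jacobian(p, x)
    h <- 1e-5
    Jfd <- vapply(seq_len(arch$n_inputs), function(s) {
      e <- numeric(arch$n_inputs); e[s] <- h
      (mlp_forward(p, x + e) - mlp_forward(p, x - e)) / (2 * h)
    }, numeric(arch$n_outputs))
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("error function is the mean squared residual norm", {
  arch <- mlp_architecture(1, 1, 1)
  zero <- constant_net(arch, 0)
  # perfect network -> 0
  rec0 <- mlp_records(matrix(c(1, 2)), c(0, 0))
  expect_equal(error_function(zero, rec0), 0)
  # one record, residual 1 -> E = 1
  expect_equal(error_function(zero, mlp_records(matrix(3), 1)), 1)
  # residuals (0.1, -0.3) -> (0.01 + 0.09)/2
  rec <- mlp_records(matrix(c(1, 2)), c(0.1, -0.3))
  expect_equal(error_function(zero, rec), 0.05, tolerance = 1e-12)
  expect_error(mlp_records(matrix(numeric(0)), numeric(0)), "at least one")
})

test_that("training fits a linear target and is seed-deterministic", {
  set.seed(1)
  x <- matrix(runif(2000, -1, 1), ncol = 1)
  y <- 0.5 * x
  tr <- mlp_records(x[1:1000, , drop = FALSE], y[1:1000])
  te <- mlp_records(x[1001:2000, , drop = FALSE], y[1001:2000])
  opts <- training_options(max_epochs = 400, patience = 100, seed = 1)
  fit <- train_mlp(tr, te, mlp_architecture(1, 5, 1), opts)
  expect_lt(fit$history$test_rmse, 0.01)
  # selected epoch attains the recorded minimum
  expect_equal(min(c(fit$history$initial_test_error,
                     fit$history$test_error)),
               fit$history$test_rmse^2, tolerance = 1e-12)
  # determinism
  fit2 <- train_mlp(tr, te, mlp_architecture(1, 5, 1), opts)
  expect_identical(fit$params, fit2$params)
})

test_that("the returned model never has worse test error than the start", {
  set.seed(2)
  x <- matrix(rnorm(400), ncol = 2)
  y <- rnorm(200)  # pure noise
  tr <- mlp_records(x[1:100, ], y[1:100])
  te <- mlp_records(x[101:200, ], y[101:200])
  fit <- train_mlp(tr, te, mlp_architecture(2, 5, 1),
                   training_options(max_epochs = 50, patience = 10, seed = 3))
  init <- init_weights(mlp_architecture(2, 5, 1), 3)
  expect_lte(error_function(fit$params, te), error_function(init, te))
  # no signal to fit: test RMSE cannot drop far below sd(y)
  expect_gte(fit$history$test_rmse, 0.95 * sd(te$y))
})

test_that("target_error stops training once the test error is low enough", {
  set.seed(4)
  x <- matrix(runif(600, -1, 1), ncol = 1)
  y <- 0.3 * x
  tr <- mlp_records(x[1:300, , drop = FALSE], y[1:300])
  te <- mlp_records(x[301:600, , drop = FALSE], y[301:600])
  fit <- train_mlp(tr, te, mlp_architecture(1, 3, 1),
                   training_options(max_epochs = 500, patience = 500,
                                    seed = 1, target_error = 1e-3))
  expect_lt(length(fit$history$epochs), 500)
  expect_lte(min(fit$history$test_error), 1e-3)
})

test_that("model serialization round-trips weights losslessly", {
  p <- init_weights(mlp_architecture(5, 4, 2), 9)
  s <- suppressWarnings(fit_standardizer(matrix(rnorm(50), ncol = 5),
                                         rnorm(10)))
  f <- tempfile(fileext = ".json")
  write_mlp(p, f, standardizer = s, metadata = list(note = "round-trip"))
  back <- read_mlp(f)
  expect_identical(back$params$output_weights, p$output_weights)
  expect_identical(back$params$hidden_weights, p$hidden_weights)
  expect_equal(back$standardizer$x_center, s$x_center)
  expect_equal(back$standardizer$y_scale, s$y_scale)
  expect_equal(back$metadata$note, "round-trip")
})
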