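#' Define a single-hidden-layer perceptron architecture
#'
#' The regression model used throughout this package is a multilayer
#' perceptron (MLP) with one hidden layer of hyperbolic-tangent units and a
#' linear output layer:
#' \deqn{y_q = a_{q0} + \sum_{j=1}^{k} a_{qj} \tanh\Big(b_{j0} +
#'   \sum_{i=1}^{n} b_{ji} x_i\Big), \qquad q = 1, \dots, m,}
#' where \eqn{n} is the number of inputs, \eqn{k} the number of hidden
#' neurons and \eqn{m} the number of outputs.  The production configuration
#' for chlorophyll-a gap filling is 23:30:1; the identity-mapping network
#' used for uncertainty decomposition is 1:30:1.
#'
#' @param n_inputs,n_hidden,n_outputs positive integers \eqn{n}, \eqn{k},
#'   \eqn{m}.
#' @return An object of class `mlp_architecture`.
#' @examples
#' mlp_architecture(23, 30, 1)
#' @export
mlp_architecture <- function(n_inputs, n_hidden, n_outputs = 1L) {
  n <- stopifnot_scalar_int(n_inputs, "n_inputs", min = 1)
  k <- stopifnot_scalar_int(n_hidden, "n_hidden", min = 1)
  m <- stopifnot_scalar_int(n_outputs, "n_outputs", min = 1)
  structure(list(n_inputs = n, n_hidden = k, n_outputs = m),
            class = "mlp_architecture")
}

#' @export
print.mlp_architecture <- function(x, ...) {
  cat(sprintf("MLP architecture %d:%d:%d (inputs:hidden:outputs)\n",
              x$n_inputs, x$n_hidden, x$n_outputs))
  invisible(x)
}

#' Initialize MLP weights
#'
#' Draws zero-mean uniform weights with scale `1/sqrt(fan_in + 1)` for each
#' layer (the +1 accounts for the bias input).  Deterministic given
#' `(arch, seed)`; distinct seeds give distinct weights, which is how
#' ensemble members are diversified.
#'
#' @param arch an [mlp_architecture()].
#' @param seed integer seed.
#' @return An object of class `mlp_params` with elements `arch`,
#'   `output_weights` (matrix `a`, `m x (k+1)`, column 1 is the bias
#'   \eqn{a_{q0}}) and `hidden_weights` (matrix `b`, `k x (n+1)`, column 1 is
#'   the bias \eqn{b_{j0}}).
#' @export
init_weights <- function(arch, seed) {
  stopifnot(inherits(arch, "mlp_architecture"))
  seed <- stopifnot_scalar_int(seed, "seed")
  n <- arch$n_inputs; k <- arch$n_hidden; m <- arch$n_outputs
  with_seed(seed, {
    sb <- 1 / sqrt(n + 1)
    sa <- 1 / sqrt(k + 1)
    b <- matrix(stats::runif(k * (n + 1), -sb, sb), nrow = k)
    a <- matrix(stats::runif(m * (k + 1), -sa, sa), nrow = m)
    new_mlp_params(arch, a, b)
  })
}

new_mlp_params <- function(arch, a, b) {
  stopifnot(is.matrix(a), is.matrix(b),
            nrow(a) == arch$n_outputs, ncol(a) == arch$n_hidden + 1L,
            nrow(b) == arch$n_hidden, ncol(b) == arch$n_inputs + 1L,
            all(is.finite(a)), all(is.finite(b)))
  structure(list(arch = arch, output_weights = a, hidden_weights = b),
            class = "mlp_params")
}

#' @export
print.mlp_params <- function(x, ...) {
  cat(sprintf("MLP parameters for architecture %d:%d:%d (%d weights)\n",
              x$arch$n_inputs, x$arch$n_hidden, x$arch$n_outputs,
              length(x$output_weights) + length(x$hidden_weights)))
  invisible(x)
}

# Hidden-layer activations for a batch: X is N x n, returns N x k.
mlp_hidden <- function(params, X) {
  b <- params$hidden_weights
  tanh(sweep(X %*% t(b[, -1, drop = FALSE]), 2, -b[, 1], "-"))
}

#' Evaluate the network on a batch of inputs
#'
#' Computes the linear-output tanh MLP exactly; no activation or clipping is
#' applied to the output, so (for the gap-filling application) negative
#' chlorophyll-a predictions are possible and reported as-is.
#'
#' @param params an `mlp_params` object.
#' @param x a numeric vector of length `n_inputs`, or an `N x n_inputs`
#'   matrix of row-wise inputs.
#' @return For a vector input, a numeric vector of length `n_outputs`; for a
#'   matrix input, an `N x n_outputs` matrix.
#' @export
mlp_forward <- function(params, x) {
  stopifnot(inherits(params, "mlp_params"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != params$arch$n_inputs) {
    stop(sprintf("input has %d components; architecture expects %d",
                 ncol(X), params$arch$n_inputs), call. = FALSE)
  }
  if (!all(is.finite(X))) stop("inputs must be finite", call. = FALSE)
  a <- params$output_weights
  H <- mlp_hidden(params, X)
  Y <- sweep(H %*% t(a[, -1, drop = FALSE]), 2, -a[, 1], "-")
  if (vec) drop(Y[1L, ]) else Y
}

#' Analytic Jacobian of the network output with respect to its inputs
#'
#' Direct differentiation of the linear-output tanh MLP gives
#' \deqn{\partial y_q / \partial x_s = \sum_{j=1}^{k} a_{qj}\,(1 - t_j^2)\,
#'   b_{js}, \qquad t_j = \tanh\Big(b_{j0} + \sum_i b_{ji} x_i\Big).}
#' The Jacobian is the basis of the input-sensitivity ranking; because the
#' derivative of a statistical model is ill-posed, downstream analyses use
#' the ensemble-averaged Jacobian (see [ensemble_jacobian()]) rather than a
#' single network's.
#'
#' @inheritParams mlp_forward
#' @param x a numeric input vector of length `n_inputs`.
#' @return A `n_outputs x n_inputs` matrix of first derivatives.
#' @export
mlp_jacobian <- function(params, x) {
  stopifnot(inherits(params, "mlp_params"))
  if (!is.null(dim(x))) x <- drop(x)
  if (length(x) != params$arch$n_inputs) {
    stop(sprintf("input has %d components; architecture expects %d",
                 length(x), params$arch$n_inputs), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("inputs must be finite", call. = FALSE)
  a <- params$output_weights[, -1, drop = FALSE]   # m x k
  b <- params$hidden_weights                       # k x (n+1)
  t_j <- drop(mlp_hidden(params, matrix(x, nrow = 1L)))
  (a * rep(1 - t_j^2, each = nrow(a))) %*% b[, -1, drop = FALSE]
}

#' Bundle input/target pairs for training and evaluation
#'
#' @param x an `N x n` numeric matrix of inputs (one record per row).
#' @param y targets: a numeric vector (single output) or `N x m` matrix.
#' @return A list of class `mlp_records` with elements `x` and `y` (always a
#'   matrix).
#' @export
mlp_records <- function(x, y) {
  x <- as.matrix(x)
  y <- if (is.null(dim(y))) matrix(y, ncol = 1L) else as.matrix(y)
  if (nrow(x) == 0L) stop("at least one record is required", call. = FALSE)
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows",
                               call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("records must be finite", call. = FALSE)
  }
  structure(list(x = x, y = y), class = "mlp_records")
}

#' Mean-squared-error function of a network over a record set
#'
#' The training criterion \eqn{E = \frac{1}{N}\sum_{i=1}^{N}
#' \lVert Y_i - \mathrm{NN}(X_i)\rVert^2}; for a single output this is the
#' ordinary mean squared error.
#'
#' @inheritParams mlp_forward
#' @param records an [mlp_records()] object.
#' @return A single nonnegative number.
#' @export
error_function <- function(params, records) {
  stopifnot(inherits(records, "mlp_records"))
  resid <- records$y - mlp_forward(params, records$x)
  sum(resid^2) / nrow(records$x)
}

#' Training options for the MLP optimizer
#'
#' Training minimizes the mean-squared-error criterion with seeded
#' mini-batch Adam and early stopping on a held-out test set: the weights
#' returned are those of the epoch with the lowest recorded test error, and
#' training halts after `patience` epochs without a test-set improvement.
#' `target_error` optionally stops training as soon as the test error drops
#' to (or below) a prescribed noise level \eqn{\varepsilon^2}; it is off by
#' default because the noise level is generally unknown a priori.
#'
#' @param max_epochs maximum number of passes over the training data.
#' @param patience early-stopping patience, in epochs; must not exceed
#'   `max_epochs`.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size (capped at the training-set size).
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param target_error optional nonnegative bound on the test-set error
#'   function at which training may stop.
#' @return A list of class `mlp_training_options`.
#' @export
training_options <- function(max_epochs = 500L, patience = 50L,
                             learning_rate = 0.01, batch_size = 1024L,
                             seed = 1L, target_error = NULL) {
  max_epochs <- stopifnot_scalar_int(max_epochs, "max_epochs", min = 1)
  patience <- stopifnot_scalar_int(patience, "patience", min = 1)
  if (patience > max_epochs) stop("`patience` must be <= `max_epochs`",
                                  call. = FALSE)
  stopifnot(is.numeric(learning_rate), learning_rate > 0)
  batch_size <- stopifnot_scalar_int(batch_size, "batch_size", min = 1)
  seed <- stopifnot_scalar_int(seed, "seed")
  if (!is.null(target_error)) {
    stopifnot(is.numeric(target_error), length(target_error) == 1L,
              target_error >= 0)
  }
  structure(list(max_epochs = max_epochs, patience = patience,
                 learning_rate = learning_rate, batch_size = batch_size,
                 seed = seed, target_error = target_error),
            class = "mlp_training_options")
}

#' Train a single network with early stopping
#'
#' Minimizes the mean-squared-error function on the training records with
#' mini-batch Adam, monitoring the error on the test records every epoch.
#' The returned parameters are those attaining the minimum recorded test
#' error (the initial weights count as epoch 0, so the returned network is
#' never worse on the test set than the initial one).  Fully deterministic
#' given the data, architecture and options.
#'
#' Inputs are assumed pre-standardized (see [fit_standardizer()]); the
#' optimizer makes no attempt to rescale them.
#'
#' @param train,test [mlp_records()] for training and test (early-stopping)
#'   sets.
#' @param arch an [mlp_architecture()].
#' @param opts an [training_options()] list.
#' @return A list with elements `params` (the selected `mlp_params`) and
#'   `history` (class `mlp_training_history`: per-epoch train/test error, the
#'   selected epoch and the final test RMSE).
#' @export
train_mlp <- function(train, test, arch, opts = training_options()) {
  stopifnot(inherits(train, "mlp_records"), inherits(test, "mlp_records"),
            inherits(arch, "mlp_architecture"),
            inherits(opts, "mlp_training_options"))
  if (ncol(train$x) != arch$n_inputs || ncol(train$y) != arch$n_outputs) {
    stop("training records do not match the architecture", call. = FALSE)
  }
  n_train <- nrow(train$x)
  bs <- min(opts$batch_size, n_train)

  params <- init_weights(arch, opts$seed)
  a <- params$output_weights
  b <- params$hidden_weights
  # Adam state, one slot per weight matrix
  ma <- a * 0; va <- a * 0; mb <- b * 0; vb <- b * 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; lr <- opts$learning_rate
  step <- 0L

  eval_error <- function(a, b, rec) {
    p <- new_mlp_params(arch, a, b)
    error_function(p, rec)
  }

  train_err <- numeric(0)
  test_err <- numeric(0)
  e_test0 <- eval_error(a, b, test)
  best <- list(a = a, b = b, err = e_test0, epoch = 0L)
  since_best <- 0L

  with_seed(opts$seed + 1L, {
    for (epoch in seq_len(opts$max_epochs)) {
      idx <- sample.int(n_train)
      for (start in seq(1L, n_train, by = bs)) {
        rows <- idx[start:min(start + bs - 1L, n_train)]
        X <- train$x[rows, , drop = FALSE]
        Y <- train$y[rows, , drop = FALSE]
        nb <- length(rows)

        H <- tanh(sweep(X %*% t(b[, -1, drop = FALSE]), 2, -b[, 1], "-"))
        Yhat <- sweep(H %*% t(a[, -1, drop = FALSE]), 2, -a[, 1], "-")
        D <- (Yhat - Y) * (2 / nb)                      # dE/dYhat
        if (!all(is.finite(D))) {
          stop("training diverged: non-finite loss gradient at epoch ",
               epoch, call. = FALSE)
        }
        ga <- cbind(colSums(D), t(D) %*% H)             # m x (k+1)
        G <- (D %*% a[, -1, drop = FALSE]) * (1 - H^2)  # N x k
        gb <- cbind(colSums(G), t(G) %*% X)             # k x (n+1)

        step <- step + 1L
        c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
        ma <- beta1 * ma + (1 - beta1) * ga
        va <- beta2 * va + (1 - beta2) * ga^2
        a <- a - lr * (ma / c1) / (sqrt(va / c2) + eps)
        mb <- beta1 * mb + (1 - beta1) * gb
        vb <- beta2 * vb + (1 - beta2) * gb^2
        b <- b - lr * (mb / c1) / (sqrt(vb / c2) + eps)
      }

      e_tr <- eval_error(a, b, train)
      e_te <- eval_error(a, b, test)
      if (!is.finite(e_tr) || !is.finite(e_te)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      }
      train_err[epoch] <- e_tr
      test_err[epoch] <- e_te
      if (e_te < best$err) {
        best <- list(a = a, b = b, err = e_te, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (!is.null(opts$target_error) && e_te <= opts$target_error) break
      if (since_best >= opts$patience) break
    }
  })

  params <- new_mlp_params(arch, best$a, best$b)
  history <- structure(
    list(epochs = seq_along(train_err),
         train_error = train_err,
         test_error = test_err,
         initial_test_error = e_test0,
         selected_epoch = best$epoch,
         test_rmse = sqrt(best$err / arch$n_outputs)),
    class = "mlp_training_history")
  list(params = params, history = history)
}

#' @export
print.mlp_training_history <- function(x, ...) {
  cat(sprintf(
    "MLP training: %d epochs run, epoch %d selected, test RMSE %.6g\n",
    length(x$epochs), x$selected_epoch, x$test_rmse))
  invisible(x)
}

#' Write or read a trained network as a self-describing JSON file
#'
#' Stores the architecture, both weight matrices at full double precision,
#' the training seed and optionally the standardization constants and free
#' metadata.  The decimal representation round-trips losslessly.
#'
#' @param params an `mlp_params` object.
#' @param path file path.
#' @param standardizer optional [fit_standardizer()] result trained with the
#'   network.
#' @param metadata optional named list of additional fields to store.
#' @return `write_mlp` returns `path` invisibly; `read_mlp` returns a list
#'   with elements `params`, `standardizer` and `metadata`.
#' @export
write_mlp <- function(params, path, standardizer = NULL, metadata = NULL) {
  stopifnot(inherits(params, "mlp_params"))
  obj <- list(
    format = "ocgapfill-mlp-1",
    arch = unclass(params$arch),
    output_weights = as.vector(params$output_weights),
    hidden_weights = as.vector(params$hidden_weights),
    standardizer = if (!is.null(standardizer)) unclass(standardizer),
    metadata = metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ocgapfill-mlp-1")) {
    stop("not an ocgapfill MLP model file: ", path, call. = FALSE)
  }
  arch <- mlp_architecture(obj$arch$n_inputs, obj$arch$n_hidden,
                           obj$arch$n_outputs)
  a <- matrix(obj$output_weights, nrow = arch$n_outputs)
  b <- matrix(obj$hidden_weights, nrow = arch$n_hidden)
  std <- if (!is.null(obj$standardizer)) {
    s <- obj$standardizer
    structure(lapply(s, unlist), class = "standardizer")
  }
  list(params = new_mlp_params(arch, a, b), standardizer = std,
       metadata = obj$metadata)
}
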