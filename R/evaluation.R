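#' Bias, RMSE and correlation of predictions against observations
#'
#' The sign convention is observation minus prediction (a positive bias
#' means the network underestimates the observed chlorophyll-a):
#' `bias = mean(obs - pred)`, `rmse = sqrt(mean((obs - pred)^2))`, `cc` the
#' Pearson correlation of predictions and observations.  The correlation is
#' reported as `NA` when either argument has zero variance (including the
#' degenerate perfect-but-constant case).
#'
#' @param pred,obs equal-length numeric vectors (mg/m3 for chlorophyll-a).
#' @return A one-row data frame with columns `bias`, `rmse`, `cc`, `n`.
#' @export
compute_metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ",
                                        call. = FALSE)
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  d <- obs - pred
  cc <- if (length(pred) >= 2L && stats::sd(pred) > 0 && stats::sd(obs) > 0) {
    stats::cor(pred, obs)
  } else NA_real_
  data.frame(bias = mean(d), rmse = sqrt(mean(d^2)), cc = cc,
             n = length(pred))
}

#' Keep records at or below a chlorophyll-a threshold
#'
#' High chlorophyll-a concentrations (above about 1 mg/m3, roughly 0.2% of
#' open-ocean data) are too sparse to train on and dominate the error
#' statistics; diagnostics are therefore reported both with and without
#' them.  The boundary value is kept (`obs <= max_chla`).
#'
#' @param obs observed chlorophyll-a values (mg/m3), or an
#'   `encoded_records` object (filtered on its `y`).
#' @param max_chla threshold, default 1.0 mg/m3.
#' @return For a vector, a logical keep-mask; for `encoded_records`, the
#'   filtered records.
#' @export
filter_threshold <- function(obs, max_chla = 1.0) {
  if (inherits(obs, "encoded_records")) {
    keep <- !is.na(obs$y) & obs$y <= max_chla
    out <- obs
    out$x <- obs$x[keep, , drop = FALSE]
    out$y <- obs$y[keep]
    out$meta <- obs$meta[keep, , drop = FALSE]
    return(out)
  }
  !is.na(obs) & obs <= max_chla
}

#' Binned error statistics over observed chlorophyll-a
#'
#' Assigns records to bins by their OBSERVED value using half-open intervals
#' `[lo, hi)` (the last bin is closed) and reports per-bin count, fraction
#' of the data, bias, RMSE and the standard deviation of the residuals
#' (obs - pred).  Records outside the edge range are collected in an
#' `overflow` row so counts always sum to `N`.
#'
#' @param pred,obs equal-length numeric vectors.
#' @param edges strictly increasing bin edges; default 20 equal-width bins
#'   over [0, 2] mg/m3.
#' @return A data frame of class `binned_stats` with one row per bin plus an
#'   overflow row when needed.
#' @export
binned_stats <- function(pred, obs, edges = seq(0, 2, length.out = 21)) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ",
                                        call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("`edges` must be strictly increasing", call. = FALSE)
  }
  nb <- length(edges) - 1L
  bin <- findInterval(obs, edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > nb] <- nb + 1L  # overflow
  rows <- lapply(seq_len(nb + 1L), function(i) {
    sel <- bin == i
    cnt <- sum(sel)
    if (cnt == 0L) {
      data.frame(bin = i, lo = NA_real_, hi = NA_real_, count = 0L,
                 fraction = 0, bias = NA_real_, rmse = NA_real_,
                 resid_sd = NA_real_)
    } else {
      d <- obs[sel] - pred[sel]
      data.frame(bin = i, lo = NA_real_, hi = NA_real_, count = cnt,
                 fraction = cnt / length(obs), bias = mean(d),
                 rmse = sqrt(mean(d^2)),
                 resid_sd = if (cnt > 1L) stats::sd(d) else 0)
    }
  })
  out <- do.call(rbind, rows)
  out$lo[seq_len(nb)] <- edges[-length(edges)]
  out$hi[seq_len(nb)] <- edges[-1]
  is_over <- out$bin == nb + 1L
  if (any(is_over) && out$count[is_over] == 0L) out <- out[!is_over, ]
  else out$bin[is_over] <- NA_integer_
  rownames(out) <- NULL
  class(out) <- c("binned_stats", "data.frame")
  out
}

#' Daily global metric time series
#'
#' Computes bias/RMSE/correlation per day over all grid cells with both an
#' observation and a prediction, optionally after removing observations
#' above the chlorophyll-a threshold.  Days with no valid points are kept in
#' the series with `NA` metrics and `n = 0`.
#'
#' Global statistics are unweighted over valid grid points by default;
#' `area_weight = TRUE` weights each cell by the cosine of its latitude.
#'
#' @param g an `ocean_grid` carrying a `chla_pred` array (see
#'   [fill_gaps()]).
#' @param apply_filter logical; drop observations above `threshold`.
#' @param threshold mg/m3, default 1.0.
#' @param area_weight logical; cos(latitude) weighting of the global means.
#' @return A data frame of class `metric_series`: one row per day with
#'   `itime`, `year`, `day`, `n`, `bias`, `rmse`, `cc`.
#' @export
daily_metric_series <- function(g, apply_filter = FALSE, threshold = 1.0,
                                area_weight = FALSE) {
  stopifnot(inherits(g, "ocean_grid"), !is.null(g$chla_pred))
  nt <- g$n_days
  w_cell <- if (area_weight) {
    matrix(cos(g$lat * pi / 180), nrow = g$nlat, ncol = g$nlon)
  } else matrix(1, g$nlat, g$nlon)
  rows <- lapply(seq_len(nt), function(t) {
    obs <- g$chla[, , t]
    pred <- g$chla_pred[, , t]
    sel <- !is.na(obs) & !is.na(pred)
    if (apply_filter) sel <- sel & obs <= threshold
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(itime = t, year = g$years[t], day = g$day_of_year[t],
                        n = 0L, bias = NA_real_, rmse = NA_real_,
                        cc = NA_real_))
    }
    o <- obs[sel]; p <- pred[sel]; w <- w_cell[sel]; w <- w / sum(w)
    d <- o - p
    cc <- if (n >= 2L && stats::sd(p) > 0 && stats::sd(o) > 0) {
      if (area_weight) stats::cov.wt(cbind(p, o), wt = w, cor = TRUE)$cor[1, 2]
      else stats::cor(p, o)
    } else NA_real_
    data.frame(itime = t, year = g$years[t], day = g$day_of_year[t], n = n,
               bias = sum(w * d), rmse = sqrt(sum(w * d^2)), cc = cc)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_series", "data.frame")
  out
}

#' Time-mean spatial bias map
#'
#' Per-grid-cell time mean of (observed - predicted) chlorophyll-a over all
#' days with both values, optionally excluding observations above the
#' threshold.  Cells with no valid data (including land) are `NA`.
#'
#' @inheritParams daily_metric_series
#' @return An `nlat x nlon` matrix with `dimnames` set to the latitude and
#'   longitude axes.
#' @export
spatial_bias_map <- function(g, apply_filter = FALSE, threshold = 1.0) {
  stopifnot(inherits(g, "ocean_grid"), !is.null(g$chla_pred))
  resid <- g$chla - g$chla_pred
  if (apply_filter) resid[!is.na(g$chla) & g$chla > threshold] <- NA
  bias <- apply(resid, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  dimnames(bias) <- list(lat = format(g$lat), lon = format(g$lon))
  bias
}

#' Sweep the hidden-layer size and pick the best-performing network
#'
#' Trains one network per candidate hidden size `k` (same seed policy and
#' options for all) and reports the test RMSE of each; the selected `k`
#' minimizes the test RMSE, with ties broken toward the smaller network
#' (parsimony).  Past the optimal size the network starts fitting the noise
#' in the data, so the test RMSE flattens or rises; the RMSE at the optimum
#' also estimates the overall uncertainty level of the data.
#'
#' @inheritParams train_mlp
#' @param k_values positive integers to try.
#' @param seed seed used for every candidate.
#' @return A data frame of class `hidden_size_sweep` with columns `k` and
#'   `test_rmse`, and attribute `best_k`.
#' @export
hidden_size_sweep <- function(train, test, k_values, seed = 1L,
                              opts = training_options()) {
  if (length(k_values) == 0L) stop("`k_values` is empty", call. = FALSE)
  k_values <- sort(unique(as.integer(k_values)))
  o <- opts
  o$seed <- stopifnot_scalar_int(seed, "seed")
  rmse <- vapply(k_values, function(k) {
    arch <- mlp_architecture(ncol(train$x), k, ncol(train$y))
    train_mlp(train, test, arch, o)$history$test_rmse
  }, numeric(1))
  out <- data.frame(k = k_values, test_rmse = rmse)
  attr(out, "best_k") <- k_values[which.min(rmse)]  # first = smallest k on tie
  class(out) <- c("hidden_size_sweep", "data.frame")
  out
}

#' Approximation-error estimate via an identity-mapping network
#'
#' The total prediction RMSE decomposes as
#' `RMSE = eps_app + eps`, where `eps_app` is the approximation error of the
#' network machinery itself and `eps` the irreducible uncertainty from
#' subgrid variability and observation noise.  `eps_app` is estimated by
#' training a network with ONE input and one output — the same chlorophyll-a
#' value — i.e. a network that must emulate the identity mapping; any test
#' error it shows is pure approximation error.  Records alternate between
#' training and test sets, mirroring the main pipeline's split.
#'
#' @param values numeric vector of at least 1000 target values (mg/m3).
#' @param k hidden-layer size of the identity network, default 30.
#' @param seed integer seed.
#' @param opts [training_options()]; the default here runs more epochs than
#'   the general default since the identity fit must be very tight.
#' @return A list of class `uncertainty_decomposition_fit` with `eps_app`
#'   (test RMSE in mg/m3), `cc` (correlation of the identity network's
#'   output with its input on the test set), and the trained `params`,
#'   `standardizer`, `history`.
#' @export
estimate_epsilon_app <- function(values, k = 30L, seed = 1L,
                                 opts = training_options(
                                   max_epochs = 400L, patience = 60L,
                                   learning_rate = 0.005,
                                   batch_size = 512L)) {
  values <- as.numeric(values)
  if (length(values) < 1000L) {
    stop("need at least 1000 values to estimate eps_app", call. = FALSE)
  }
  if (stats::sd(values) == 0) stop("constant targets: eps_app undefined",
                                   call. = FALSE)
  idx <- seq_along(values)
  tr <- values[idx %% 2L == 1L]  # alternating split: odd rows train
  te <- values[idx %% 2L == 0L]
  s <- fit_standardizer(matrix(tr, ncol = 1L), tr)
  make <- function(v) mlp_records(apply_standardizer(s, matrix(v, ncol = 1L)),
                                  standardize_y(s, v))
  o <- opts
  o$seed <- stopifnot_scalar_int(seed, "seed")
  fit <- train_mlp(make(tr), make(te), mlp_architecture(1L, k, 1L), o)
  pred <- unstandardize_y(
    s, drop(mlp_forward(fit$params,
                        apply_standardizer(s, matrix(te, ncol = 1L)))))
  m <- compute_metrics(pred, te)
  structure(list(eps_app = m$rmse, cc = m$cc, params = fit$params,
                 standardizer = s, history = fit$history),
            class = "uncertainty_decomposition_fit")
}

#' Decompose a total RMSE into approximation and data-uncertainty parts
#'
#' @param total_rmse total prediction RMSE (mg/m3).
#' @param eps_app approximation error from [estimate_epsilon_app()] (a
#'   number or the fit object).
#' @return A data frame with `rmse`, `eps_app` and `epsilon`
#'   (`= max(rmse - eps_app, 0)`), all nonnegative.
#' @export
uncertainty_decomposition <- function(total_rmse, eps_app) {
  if (inherits(eps_app, "uncertainty_decomposition_fit")) {
    eps_app <- eps_app$eps_app
  }
  stopifnot(is.numeric(total_rmse), total_rmse >= 0, eps_app >= 0)
  data.frame(rmse = total_rmse, eps_app = eps_app,
             epsilon = max(total_rmse - eps_app, 0))
}
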