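#' Train an ensemble of identically architected networks
#'
#' Gap-filled chlorophyll-a fields are produced by an ensemble of networks
#' (default six, each 23:30:1) that share the same training and test data
#' and differ only in the random initialization of their weights, so that
#' different members settle into different local minima of the error
#' function.  The ensemble average reduces the random component of the
#' prediction error and stabilizes the Jacobian used for sensitivity
#' analysis.  Member seeds are `base_seed + 0 .. n_members - 1`.
#'
#' @inheritParams train_mlp
#' @param n_members number of ensemble members (default 6).
#' @param base_seed integer; member `i` trains with seed `base_seed + i - 1`.
#' @param standardizer optional [fit_standardizer()] result (with target
#'   constants) attached to the ensemble so predictions can be returned in
#'   physical units.
#' @return An object of class `mlp_ensemble`: list with `members` (list of
#'   `mlp_params`), `histories`, `arch`, `seeds`, `standardizer`.
#' @export
train_ensemble <- function(train, test, arch, n_members = 6L,
                           base_seed = 1L, opts = training_options(),
                           standardizer = NULL) {
  n_members <- stopifnot_scalar_int(n_members, "n_members", min = 1)
  base_seed <- stopifnot_scalar_int(base_seed, "base_seed")
  seeds <- base_seed + seq_len(n_members) - 1L
  members <- vector("list", n_members)
  histories <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    o <- opts
    o$seed <- seeds[i]
    fit <- tryCatch(train_mlp(train, test, arch, o), error = function(e) {
      stop(sprintf("ensemble member %d (seed %d) failed to train: %s",
                   i, seeds[i], conditionMessage(e)), call. = FALSE)
    })
    members[[i]] <- fit$params
    histories[[i]] <- fit$history
  }
  new_ensemble(members, histories, arch, seeds, standardizer)
}

new_ensemble <- function(members, histories, arch, seeds,
                         standardizer = NULL) {
  stopifnot(length(members) >= 1L, length(seeds) == length(members),
            !anyDuplicated(seeds))
  structure(list(members = members, histories = histories, arch = arch,
                 seeds = as.integer(seeds), standardizer = standardizer),
            class = "mlp_ensemble")
}

#' @export
print.mlp_ensemble <- function(x, ...) {
  cat(sprintf("MLP ensemble: %d member(s), architecture %d:%d:%d, seeds %s\n",
              length(x$members), x$arch$n_inputs, x$arch$n_hidden,
              x$arch$n_outputs, paste(x$seeds, collapse = ", ")))
  invisible(x)
}

# member predictions as an N x n_members matrix (single-output ensembles)
member_predictions <- function(e, x, standardized = FALSE) {
  xs <- if (!standardized && !is.null(e$standardizer)) {
    apply_standardizer(e$standardizer, x)
  } else if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  P <- vapply(e$members, function(p) drop(mlp_forward(p, xs)),
              numeric(nrow(xs)))
  P <- matrix(P, nrow = nrow(xs))
  if (!standardized && !is.null(e$standardizer) &&
      !is.null(e$standardizer$y_scale)) {
    P <- unstandardize_y(e$standardizer, P)
  }
  P
}

#' Ensemble-mean prediction with member spread
#'
#' The ensemble prediction is the arithmetic mean of the member outputs; the
#' spread is the sample (n-1 denominator) standard deviation across members,
#' both in physical units (mg/m3) when the ensemble carries a standardizer.
#' With a single member the spread is reported as 0.
#'
#' @param e an `mlp_ensemble`.
#' @param x input vector or `N x n` matrix.  If the ensemble has a
#'   standardizer attached, `x` is expected in raw (encoded, unstandardized)
#'   units and standardization is applied internally; set
#'   `standardized = TRUE` to bypass.
#' @param standardized logical; `x` (and the returned values) are already in
#'   standardized space.
#' @return A list with numeric vectors `mean` and `spread` (length `N`).
#' @export
ensemble_predict <- function(e, x, standardized = FALSE) {
  stopifnot(inherits(e, "mlp_ensemble"))
  if (length(e$members) == 0L) stop("empty ensemble", call. = FALSE)
  P <- member_predictions(e, x, standardized)
  spread <- if (ncol(P) > 1L) apply(P, 1, stats::sd) else rep(0, nrow(P))
  list(mean = rowMeans(P), spread = spread)
}

#' Ensemble-averaged Jacobian input-sensitivity report
#'
#' Computes, for every member and every evaluation record, the analytic
#' Jacobian of the (single) output with respect to the inputs; takes the
#' mean absolute value per input across records, and averages across
#' members.  Because the derivative of a statistical model is an ill-posed
#' quantity, this ensemble average is the stable sensitivity estimate; the
#' induced descending ranking identifies which physical and metadata inputs
#' drive the predicted chlorophyll-a.
#'
#' By default the Jacobian is taken in standardized input/output space so
#' that inputs with different physical units (degC vs g/kg vs m) are
#' comparable; `physical_units = TRUE` rescales to physical units
#' (mg/m3 per input unit) instead.
#'
#' @param e an `mlp_ensemble` (single-output).
#' @param x evaluation inputs, an `N x n` matrix in raw encoded units when
#'   the ensemble has a standardizer (typically the test set).
#' @param physical_units logical; report d(chla)/d(input) in physical units.
#' @return A data frame of class `sensitivity_report` with columns `input`
#'   (index), `name`, `mean_abs_jacobian`, `rank` (1 = most influential).
#' @export
ensemble_jacobian <- function(e, x, physical_units = FALSE) {
  stopifnot(inherits(e, "mlp_ensemble"))
  if (e$arch$n_outputs != 1L) {
    stop("sensitivity report is defined for single-output ensembles",
         call. = FALSE)
  }
  xs <- if (!is.null(e$standardizer)) apply_standardizer(e$standardizer, x)
        else if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (nrow(xs) == 0L) stop("evaluation set is empty", call. = FALSE)
  n <- e$arch$n_inputs
  acc <- numeric(n)
  for (p in e$members) {
    a1 <- drop(p$output_weights[, -1, drop = FALSE])     # length k
    b1 <- p$hidden_weights[, -1, drop = FALSE]           # k x n
    H <- mlp_hidden(p, xs)                               # N x k
    J <- ((1 - H^2) * rep(a1, each = nrow(H))) %*% b1    # N x n
    acc <- acc + colMeans(abs(J))
  }
  sens <- acc / length(e$members)
  if (physical_units) {
    s <- e$standardizer
    if (is.null(s)) stop("no standardizer attached; physical units unknown",
                         call. = FALSE)
    sens <- sens * s$y_scale / s$x_scale
  }
  nm <- colnames(xs) %||% paste0("x", seq_len(n))
  out <- data.frame(input = seq_len(n), name = nm,
                    mean_abs_jacobian = unname(sens))
  out$rank <- rank(-out$mean_abs_jacobian, ties.method = "first")
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Write a sensitivity report as CSV
#'
#' @param report a `sensitivity_report`.
#' @param path file path.
#' @export
write_sensitivity_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Serialize an ensemble as a directory of model files with a manifest
#'
#' Each member is written with [write_mlp()] as `member_<i>.json`; the
#' manifest records the architecture, seeds and member file names.
#' `read_ensemble()` restores the ensemble losslessly.
#'
#' @param e an `mlp_ensemble`.
#' @param dir directory path (created if needed).
#' @return `write_ensemble` returns `dir` invisibly; `read_ensemble` an
#'   `mlp_ensemble`.
#' @export
write_ensemble <- function(e, dir) {
  stopifnot(inherits(e, "mlp_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("member_%d.json", seq_along(e$members))
  for (i in seq_along(e$members)) {
    write_mlp(e$members[[i]], file.path(dir, files[i]),
              metadata = list(seed = e$seeds[i]))
  }
  manifest <- list(format = "ocgapfill-ensemble-1",
                   arch = unclass(e$arch),
                   seeds = e$seeds,
                   members = files,
                   standardizer = if (!is.null(e$standardizer))
                     unclass(e$standardizer))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "ocgapfill-ensemble-1")) {
    stop("not an ocgapfill ensemble directory: ", dir, call. = FALSE)
  }
  arch <- mlp_architecture(man$arch$n_inputs, man$arch$n_hidden,
                           man$arch$n_outputs)
  members <- lapply(file.path(dir, man$members),
                    function(f) read_mlp(f)$params)
  std <- if (!is.null(man$standardizer)) {
    structure(lapply(man$standardizer, unlist), class = "standardizer")
  }
  new_ensemble(members, histories = vector("list", length(members)),
               arch = arch, seeds = man$seeds, standardizer = std)
}
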