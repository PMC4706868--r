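#' Names and order of the 23 network inputs
#'
#' The input vector concatenates six metadata components with seventeen
#' physical predictors, in this fixed order: year; sine and cosine of the
#' day-of-year angle; sine and cosine of longitude; sine of latitude;
#' sea-surface height (m); sea-surface salinity (g/kg); sea-surface
#' temperature (degC); seven upper-ocean salinity levels (g/kg); seven
#' upper-ocean temperature levels (degC).  Latitude deliberately uses only
#' its sine (no cosine component), mirroring the operational input listing.
#'
#' @return Character vector of length 23.
#' @export
input_names <- function() {
  c("year", "day_sin", "day_cos", "lon_sin", "lon_cos", "lat_sin",
    "ssh", "sss", "sst",
    paste0("sal_", 1:7), paste0("temp_", 1:7))
}

# raw-record column set expected by the encoder (besides identifiers)
raw_predictor_names <- function() {
  c("ssh", "sss", "sst", paste0("sal_", 1:7), paste0("temp_", 1:7))
}

normalize_lon <- function(lon) ((lon + 180) %% 360) - 180

#' Encode raw records into the 23-component network input
#'
#' Builds, for each record, the input vector
#' `[year, sin(tau), cos(tau), sin(lon), cos(lon), sin(lat), SSH, SSS, SST,
#' sal_1..7, temp_1..7]` with the day-of-year angle
#' `tau = 2 * pi * day / day_denominator` and longitude/latitude converted
#' to radians.  Longitudes are accepted in `[-180, 360)` and normalized to
#' `[-180, 180)` first, so e.g. -30 deg and 330 deg encode identically.
#'
#' The day-of-year denominator is 366 by default (the operational input
#' listing); 365 is also accepted as the alternative convention.
#'
#' @param raw a data frame with columns `year`, `day` (day of year, 1..366),
#'   `lon`, `lat` (degrees), `ssh`, `sss`, `sst`, `sal_1..sal_7`,
#'   `temp_1..temp_7`, and optionally `chla` (mg/m3, `NA` where missing) and
#'   identifier columns `itime`, `ilat`, `ilon`.
#' @param day_denominator 366 (default) or 365.
#' @return A list of class `encoded_records` with elements `x` (an `N x 23`
#'   matrix, columns named per [input_names()]), `y` (chlorophyll-a vector,
#'   `NA` for prediction-only records) and `meta` (identifier data frame).
#' @export
encode_records <- function(raw, day_denominator = 366) {
  stopifnot(is.data.frame(raw))
  if (!day_denominator %in% c(365, 366)) {
    stop("`day_denominator` must be 365 or 366", call. = FALSE)
  }
  needed <- c("year", "day", "lon", "lat", raw_predictor_names())
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("raw records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(raw$lat < -90 | raw$lat > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(raw$day < 1 | raw$day > 366, na.rm = TRUE)) {
    stop("day of year outside 1..366", call. = FALSE)
  }
  pred <- as.matrix(raw[raw_predictor_names()])
  if (anyNA(pred)) {
    stop("raw records contain missing physical predictors; ",
         "filter to complete records first (see assemble_records)",
         call. = FALSE)
  }
  tau <- 2 * pi * raw$day / day_denominator
  lon_r <- normalize_lon(raw$lon) * pi / 180
  lat_r <- raw$lat * pi / 180
  x <- cbind(raw$year, sin(tau), cos(tau), sin(lon_r), cos(lon_r),
             sin(lat_r), pred)
  colnames(x) <- input_names()
  meta_cols <- intersect(c("itime", "ilat", "ilon", "year", "day",
                           "lon", "lat"), names(raw))
  structure(list(x = x,
                 y = if ("chla" %in% names(raw)) raw$chla else
                   rep(NA_real_, nrow(x)),
                 meta = raw[meta_cols],
                 day_denominator = day_denominator),
            class = "encoded_records")
}

#' Encode a single raw record
#'
#' Convenience wrapper around [encode_records()] for one observation.
#'
#' @param raw a named list or one-row data frame (see [encode_records()]).
#' @inheritParams encode_records
#' @return A list with the 23-component vector `x` and target `y`.
#' @export
encode_record <- function(raw, day_denominator = 366) {
  enc <- encode_records(as.data.frame(raw), day_denominator)
  list(x = drop(enc$x[1L, ]), y = enc$y[1L])
}

#' Fit and apply per-input standardization
#'
#' `fit_standardizer()` computes per-column mean and standard deviation of
#' the training inputs (and, when targets are supplied, of the target) so
#' that training sees z-scored data; network predictions are mapped back to
#' physical units (mg/m3 for chlorophyll-a) with `unstandardize_y()`.
#' Constant columns get scale 1 (with a warning) so they map to zero rather
#' than dividing by zero.
#'
#' @param x an `N x p` training-input matrix (`N >= 2`).
#' @param y optional target vector to fit target constants.
#' @return An object of class `standardizer` with fields `x_center`,
#'   `x_scale` and, if `y` was given, `y_center`, `y_scale`.
#' @export
fit_standardizer <- function(x, y = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 records to fit a standardizer",
                         call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    warning("constant input column(s) ",
            paste(which(scl == 0), collapse = ", "),
            ": scale forced to 1")
    scl[scl == 0] <- 1
  }
  out <- list(x_center = ctr, x_scale = scl)
  if (!is.null(y)) {
    ys <- stats::sd(y)
    if (is.na(ys) || ys == 0) {
      warning("constant target: scale forced to 1")
      ys <- 1
    }
    out$y_center <- mean(y)
    out$y_scale <- ys
  }
  structure(out, class = "standardizer")
}

#' @rdname fit_standardizer
#' @param s a `standardizer`.
#' @export
apply_standardizer <- function(s, x) {
  stopifnot(inherits(s, "standardizer"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  sweep(sweep(x, 2, s$x_center, "-"), 2, s$x_scale, "/")
}

#' @rdname fit_standardizer
#' @export
unapply_standardizer <- function(s, x) {
  stopifnot(inherits(s, "standardizer"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  sweep(sweep(x, 2, s$x_scale, "*"), 2, s$x_center, "+")
}

#' @rdname fit_standardizer
#' @export
standardize_y <- function(s, y) {
  stopifnot(inherits(s, "standardizer"), !is.null(s$y_scale))
  (y - s$y_center) / s$y_scale
}

#' @rdname fit_standardizer
#' @export
unstandardize_y <- function(s, y) {
  stopifnot(inherits(s, "standardizer"), !is.null(s$y_scale))
  y * s$y_scale + s$y_center
}

#' Read or write encoded record tables as CSV
#'
#' The record-table dialect has 27 columns: three identifiers (`itime`,
#' `ilat`, `ilon`), the 23 inputs in [input_names()] order, and the `chla`
#' target (empty where missing).
#'
#' @param enc an `encoded_records` object whose `meta` carries `itime`,
#'   `ilat`, `ilon`.
#' @param path file path.
#' @return `write_records_csv` returns `path` invisibly; `read_records_csv`
#'   returns an `encoded_records` object.
#' @export
write_records_csv <- function(enc, path) {
  stopifnot(inherits(enc, "encoded_records"))
  ids <- enc$meta[intersect(c("itime", "ilat", "ilon"), names(enc$meta))]
  if (ncol(ids) != 3L) stop("records lack itime/ilat/ilon identifiers",
                            call. = FALSE)
  df <- cbind(ids, as.data.frame(enc$x), chla = enc$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path)
  expected <- c("itime", "ilat", "ilon", input_names(), "chla")
  if (!identical(names(df), expected)) {
    stop("not an ocgapfill record table: ", path, call. = FALSE)
  }
  structure(list(x = as.matrix(df[input_names()]),
                 y = df$chla,
                 meta = df[c("itime", "ilat", "ilon")],
                 day_denominator = NA_real_),
            class = "encoded_records")
}
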