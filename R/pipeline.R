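#' Construct a gridded daily ocean dataset
#'
#' Container for daily fields on a regular latitude/longitude grid: the
#' chlorophyll-a target (with gaps as `NA`), the three surface predictors,
#' and seven-level upper-ocean salinity and temperature profiles.  Land
#' cells are flagged in the `ocean` mask; any `NA` inside the ocean is a
#' missing observation (cloud/swath gap).
#'
#' @param lat,lon numeric axes of cell centers (degrees), regular spacing.
#' @param years,day_of_year integer vectors, one entry per day.
#' @param ocean `nlat x nlon` logical mask, `TRUE` for ocean cells.
#' @param ssh,sss,sst `nlat x nlon x n_days` arrays (m, g/kg, degC).
#' @param sal,temp `nlat x nlon x 7 x n_days` arrays (g/kg, degC).
#' @param chla `nlat x nlon x n_days` chlorophyll-a (mg/m3) with `NA` gaps,
#'   or `NULL` for predictor-only datasets.
#' @param chla_true optional noise-free truth (synthetic datasets only).
#' @return An object of class `ocean_grid`.
#' @export
ocean_grid <- function(lat, lon, years, day_of_year, ocean,
                       ssh, sss, sst, sal, temp,
                       chla = NULL, chla_true = NULL) {
  nlat <- length(lat); nlon <- length(lon); nt <- length(years)
  stopifnot(length(day_of_year) == nt,
            identical(dim(ocean), c(nlat, nlon)), is.logical(ocean))
  d3 <- c(nlat, nlon, nt); d4 <- c(nlat, nlon, 7L, nt)
  for (nm in c("ssh", "sss", "sst")) {
    if (!identical(dim(get(nm)), d3)) {
      stop(nm, " must be an nlat x nlon x n_days array", call. = FALSE)
    }
  }
  for (nm in c("sal", "temp")) {
    if (!identical(dim(get(nm)), d4)) {
      stop(nm, " must be an nlat x nlon x 7 x n_days array", call. = FALSE)
    }
  }
  if (!is.null(chla)) stopifnot(identical(dim(chla), d3))
  if (!is.null(chla_true)) stopifnot(identical(dim(chla_true), d3))
  structure(list(lat = lat, lon = lon, nlat = nlat, nlon = nlon,
                 n_days = nt, years = as.integer(years),
                 day_of_year = as.integer(day_of_year), ocean = ocean,
                 ssh = ssh, sss = sss, sst = sst, sal = sal, temp = temp,
                 chla = chla, chla_true = chla_true,
                 chla_pred = NULL, chla_filled = NULL, provenance = NULL),
            class = "ocean_grid")
}

#' @export
print.ocean_grid <- function(x, ...) {
  n_ocean <- sum(x$ocean)
  cat(sprintf(
    "ocean_grid: %d x %d cells (%d ocean), %d days (%s)\n",
    x$nlat, x$nlon, n_ocean, x$n_days,
    paste(range(x$years), collapse = "-")))
  if (!is.null(x$chla)) {
    miss <- mean(is.na(x$chla[rep(x$ocean, x$n_days)]))
    cat(sprintf("  chla present; %.1f%% of ocean cell-days missing\n",
                100 * miss))
  }
  if (!is.null(x$chla_filled)) cat("  gap-filled chla present\n")
  invisible(x)
}

provenance_levels <- function() c("observed", "filled", "unfillable")

#' Flatten a gridded dataset into per-(cell, day) raw records
#'
#' Emits one record per (ocean cell, day) where ALL 17 physical predictors
#' are valid, in the canonical order time-major, then latitude, then
#' longitude (the order the alternating train/test split is defined on).
#' Records with complete predictors but missing chlorophyll-a are emitted
#' with `chla = NA`: these are the gaps to fill.  Cell-days missing any
#' predictor are excluded and counted in the `excluded` attribute.
#'
#' @param g an `ocean_grid` (chla array may be absent).
#' @return A data frame with identifier columns (`itime`, `ilat`, `ilon`),
#'   metadata (`year`, `day`, `lon`, `lat`), the 17 predictors and `chla`;
#'   attributes `excluded` (count of incomplete ocean cell-days) and
#'   `missingness` (per-variable NA counts among ocean cell-days).
#' @export
assemble_records <- function(g) {
  stopifnot(inherits(g, "ocean_grid"))
  cells <- expand.grid(ilon = seq_len(g$nlon), ilat = seq_len(g$nlat),
                       itime = seq_len(g$n_days))
  # canonical order: time-major, then lat, then lon (lon varies fastest)
  ix <- cbind(cells$ilat, cells$ilon, cells$itime)
  keep_ocean <- g$ocean[ix[, 1:2, drop = FALSE]]
  pred <- cbind(ssh = g$ssh[ix], sss = g$sss[ix], sst = g$sst[ix])
  for (l in 1:7) pred <- cbind(pred, g$sal[cbind(ix[, 1:2], l, ix[, 3])])
  for (l in 1:7) pred <- cbind(pred, g$temp[cbind(ix[, 1:2], l, ix[, 3])])
  colnames(pred) <- raw_predictor_names()
  complete <- keep_ocean & rowSums(is.na(pred)) == 0L
  miss <- colSums(is.na(pred[keep_ocean, , drop = FALSE]))
  if (!any(complete)) {
    stop("no complete records; per-variable missing counts among ocean ",
         "cell-days: ",
         paste(sprintf("%s=%d", names(miss), miss), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(itime = cells$itime[complete],
                    ilat = cells$ilat[complete],
                    ilon = cells$ilon[complete])
  out$year <- g$years[out$itime]
  out$day <- g$day_of_year[out$itime]
  out$lon <- g$lon[out$ilon]
  out$lat <- g$lat[out$ilat]
  out <- cbind(out, as.data.frame(pred[complete, , drop = FALSE]))
  out$chla <- if (!is.null(g$chla)) g$chla[ix[complete, , drop = FALSE]]
              else NA_real_
  attr(out, "excluded") <- sum(keep_ocean) - sum(complete)
  attr(out, "missingness") <- miss
  out
}

#' Alternating train/test split over canonically ordered records
#'
#' Every second record goes to training: with the records in canonical
#' order (time-major, then latitude, then longitude), even 0-based indices
#' (rows 1, 3, 5, ... in R's 1-based numbering) form the training set and
#' the rest the test set, so the two sets differ in size by at most one and
#' the split is deterministic.
#'
#' @param records a data frame (or `encoded_records`) in canonical order.
#' @return A list with `train` and `test` subsets of the same type.
#' @export
alternating_split <- function(records) {
  n <- if (is.data.frame(records)) nrow(records) else nrow(records$x)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  sel <- (seq_len(n) %% 2L) == 1L
  take <- function(r, keep) {
    if (is.data.frame(r)) return(r[keep, , drop = FALSE])
    out <- r
    out$x <- r$x[keep, , drop = FALSE]
    out$y <- r$y[keep]
    out$meta <- r$meta[keep, , drop = FALSE]
    out
  }
  list(train = take(records, sel), test = take(records, !sel))
}

encoded_to_mlp <- function(enc, s) {
  mlp_records(apply_standardizer(s, enc$x), standardize_y(s, enc$y))
}

#' Train a gap-filling ensemble from a gridded dataset
#'
#' End-to-end training: assembles complete labelled records, applies the
#' alternating train/test split, encodes the 23 inputs, fits the
#' standardizer on the training set, and trains the ensemble.
#'
#' @param g an `ocean_grid` with chlorophyll-a observations.
#' @param arch an [mlp_architecture()]; default 23:30:1.
#' @param n_members ensemble size, default 6.
#' @param base_seed integer seed; member `i` uses `base_seed + i - 1`.
#' @param opts [training_options()].
#' @param day_denominator 366 (default) or 365.
#' @param max_train_records optional cap: if the training set exceeds it, a
#'   deterministic evenly spaced subsample of that size is used (and the
#'   same for the test set).
#' @return A list of class `gapfill_fit`: `ensemble`, encoded `train` and
#'   `test` records (raw units), and a `counts` list (labelled, gaps,
#'   excluded).
#' @export
gapfill_train <- function(g, arch = mlp_architecture(23, 30, 1),
                          n_members = 6L, base_seed = 1L,
                          opts = training_options(),
                          day_denominator = 366,
                          max_train_records = NULL) {
  records <- assemble_records(g)
  labelled <- records[!is.na(records$chla), , drop = FALSE]
  if (nrow(labelled) < 2L) stop("not enough labelled records", call. = FALSE)
  sp <- alternating_split(labelled)
  if (!is.null(max_train_records)) {
    thin <- function(df) {
      if (nrow(df) <= max_train_records) return(df)
      df[round(seq(1L, nrow(df), length.out = max_train_records)), ,
         drop = FALSE]
    }
    sp$train <- thin(sp$train); sp$test <- thin(sp$test)
  }
  enc_tr <- encode_records(sp$train, day_denominator)
  enc_te <- encode_records(sp$test, day_denominator)
  s <- fit_standardizer(enc_tr$x, enc_tr$y)
  e <- train_ensemble(encoded_to_mlp(enc_tr, s), encoded_to_mlp(enc_te, s),
                      arch, n_members = n_members, base_seed = base_seed,
                      opts = opts, standardizer = s)
  structure(list(ensemble = e, train = enc_tr, test = enc_te,
                 day_denominator = day_denominator,
                 counts = list(labelled = nrow(labelled),
                               gaps = sum(is.na(records$chla)),
                               excluded = attr(records, "excluded"))),
            class = "gapfill_fit")
}

#' @export
print.gapfill_fit <- function(x, ...) {
  cat(sprintf(
    "gapfill_fit: %d member(s); %d labelled records (%d train / %d test), %d gaps\n",
    length(x$ensemble$members), x$counts$labelled, nrow(x$train$x),
    nrow(x$test$x), x$counts$gaps))
  invisible(x)
}

#' Fill chlorophyll-a gaps in a gridded dataset with an ensemble
#'
#' Predicts the ensemble-mean chlorophyll-a for every (ocean cell, day)
#' whose 17 physical predictors are complete, then merges with the
#' observations: observed values are never overwritten; network values only
#' fill masked cells.  The provenance array distinguishes `"observed"`,
#' `"filled"` (gap with complete predictors) and `"unfillable"` (gap with
#' incomplete predictors); land cells are `NA` throughout.
#'
#' @param e an `mlp_ensemble` with a standardizer (or a `gapfill_fit`).
#' @param g an `ocean_grid` with chlorophyll-a observations.
#' @param day_denominator must match the encoding used in training.
#' @return `g` with three arrays added: `chla_pred` (raw ensemble mean
#'   everywhere predictable, used for validation), `chla_filled` (observed
#'   where available, else predicted) and `provenance` (character array).
#' @export
fill_gaps <- function(e, g, day_denominator = 366) {
  if (inherits(e, "gapfill_fit")) {
    day_denominator <- e$day_denominator
    e <- e$ensemble
  }
  stopifnot(inherits(e, "mlp_ensemble"), inherits(g, "ocean_grid"),
            !is.null(g$chla))
  if (e$arch$n_inputs != 23L || is.null(e$standardizer)) {
    stop("ensemble incompatible with the 23-input encoding", call. = FALSE)
  }
  records <- assemble_records(g)
  enc <- encode_records(records, day_denominator)
  pred <- ensemble_predict(e, enc$x)$mean

  d3 <- c(g$nlat, g$nlon, g$n_days)
  chla_pred <- array(NA_real_, d3)
  ix <- cbind(records$ilat, records$ilon, records$itime)
  chla_pred[ix] <- pred

  chla_filled <- g$chla
  fillable_gap <- is.na(g$chla) & !is.na(chla_pred)
  chla_filled[fillable_gap] <- chla_pred[fillable_gap]

  prov <- array(NA_character_, d3)
  ocean3 <- array(g$ocean, d3)
  prov[ocean3 & !is.na(g$chla)] <- "observed"
  prov[fillable_gap & ocean3] <- "filled"
  prov[ocean3 & is.na(chla_filled)] <- "unfillable"

  g$chla_pred <- chla_pred
  g$chla_filled <- chla_filled
  g$provenance <- prov
  g
}

#' Generalization-skill experiment across training periods
#'
#' Trains one model variant per training-year set on the labelled records of
#' those years (alternating split within the period), predicts the whole
#' record stream, and reports pooled bias/RMSE/correlation per period
#' (training vs validation years) together with the daily correlation
#' series.  A network trained on too short a period loses skill beyond its
#' training window, which this experiment quantifies.
#'
#' @param g an `ocean_grid` spanning the union of all years involved.
#' @param train_years integer vector, or a named list of integer vectors to
#'   compare several variants (e.g. one- vs two-year training).
#' @param validation_years integer vector, disjoint from every training set.
#' @inheritParams gapfill_train
#' @param apply_filter drop observations above 1 mg/m3 in the metrics.
#' @return A list of class `generalization_experiment` with `summary` (data
#'   frame: variant, period, n, bias, rmse, cc) and `daily` (per-variant
#'   daily metric series).
#' @export
generalization_experiment <- function(g, train_years, validation_years,
                                      arch = mlp_architecture(23, 30, 1),
                                      n_members = 1L, base_seed = 1L,
                                      opts = training_options(),
                                      day_denominator = 366,
                                      max_train_records = NULL,
                                      apply_filter = FALSE) {
  variants <- if (is.list(train_years)) train_years else list(train_years)
  if (is.null(names(variants))) {
    names(variants) <- vapply(variants, function(v)
      paste0("train_", paste(range(v), collapse = "-")), character(1))
  }
  for (v in variants) {
    if (length(intersect(v, validation_years))) {
      stop("training and validation years overlap", call. = FALSE)
    }
  }
  summary_rows <- list()
  daily <- list()
  for (nm in names(variants)) {
    yrs <- variants[[nm]]
    g_tr <- subset_years(g, yrs)
    fit <- gapfill_train(g_tr, arch = arch, n_members = n_members,
                         base_seed = base_seed, opts = opts,
                         day_denominator = day_denominator,
                         max_train_records = max_train_records)
    g_all <- fill_gaps(fit, g)
    ser <- daily_metric_series(g_all, apply_filter = apply_filter)
    ser$variant <- nm
    daily[[nm]] <- ser
    for (period in list(training = yrs, validation = validation_years)) {
      pn <- if (identical(period, yrs)) "training" else "validation"
      sel_t <- g$years %in% period
      obs <- g_all$chla[, , sel_t, drop = FALSE]
      prd <- g_all$chla_pred[, , sel_t, drop = FALSE]
      ok <- !is.na(obs) & !is.na(prd)
      if (apply_filter) ok <- ok & obs <= 1.0
      m <- compute_metrics(prd[ok], obs[ok])
      summary_rows[[paste(nm, pn)]] <-
        cbind(data.frame(variant = nm, period = pn), m)
    }
  }
  structure(list(summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE)),
                 daily = do.call(rbind, c(daily, make.row.names = FALSE))),
            class = "generalization_experiment")
}

# restrict a grid to the days belonging to the given years
subset_years <- function(g, years) {
  sel <- g$years %in% years
  if (!any(sel)) stop("no days in the requested years", call. = FALSE)
  ocean_grid(g$lat, g$lon, g$years[sel], g$day_of_year[sel], g$ocean,
             g$ssh[, , sel, drop = FALSE], g$sss[, , sel, drop = FALSE],
             g$sst[, , sel, drop = FALSE],
             g$sal[, , , sel, drop = FALSE], g$temp[, , , sel, drop = FALSE],
             chla = if (!is.null(g$chla)) g$chla[, , sel, drop = FALSE],
             chla_true = if (!is.null(g$chla_true))
               g$chla_true[, , sel, drop = FALSE])
}

#' Read or write a gridded dataset as long-format CSV
#'
#' One row per (day, cell) including land cells (flagged `ocean = 0`), in
#' canonical order; missing values are empty fields.  Values round-trip at
#' the full precision written; masks round-trip exactly.
#'
#' @param g an `ocean_grid`.
#' @param path file path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv` an
#'   `ocean_grid`.
#' @export
write_grid_csv <- function(g, path) {
  stopifnot(inherits(g, "ocean_grid"))
  cells <- expand.grid(ilon = seq_len(g$nlon), ilat = seq_len(g$nlat),
                       itime = seq_len(g$n_days))
  ix <- cbind(cells$ilat, cells$ilon, cells$itime)
  df <- data.frame(itime = cells$itime, ilat = cells$ilat,
                   ilon = cells$ilon,
                   year = g$years[cells$itime],
                   day = g$day_of_year[cells$itime],
                   lat = g$lat[cells$ilat], lon = g$lon[cells$ilon],
                   ocean = as.integer(g$ocean[ix[, 1:2, drop = FALSE]]),
                   ssh = g$ssh[ix], sss = g$sss[ix], sst = g$sst[ix])
  for (l in 1:7) df[[paste0("sal_", l)]] <-
    g$sal[cbind(ix[, 1:2], l, ix[, 3])]
  for (l in 1:7) df[[paste0("temp_", l)]] <-
    g$temp[cbind(ix[, 1:2], l, ix[, 3])]
  if (!is.null(g$chla)) df$chla <- g$chla[ix]
  if (!is.null(g$chla_true)) df$chla_true <- g$chla_true[ix]
  if (!is.null(g$chla_pred)) df$chla_pred <- g$chla_pred[ix]
  if (!is.null(g$chla_filled)) df$chla_filled <- g$chla_filled[ix]
  if (!is.null(g$provenance)) df$provenance <- g$provenance[ix]
  data.table::fwrite(df, path, na = "")
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path, na.strings = ""))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  nlat <- length(lat); nlon <- length(lon)
  nt <- max(df$itime)
  ord <- order(df$itime, df$ilat, df$ilon)
  df <- df[ord, , drop = FALSE]
  d3 <- c(nlat, nlon, nt)
  ix <- cbind(df$ilat, df$ilon, df$itime)
  grab3 <- function(col) {
    a <- array(NA_real_, d3); a[ix] <- df[[col]]; a
  }
  first_day <- df$itime == 1L
  ocean <- matrix(FALSE, nlat, nlon)
  ocean[cbind(df$ilat[first_day], df$ilon[first_day])] <-
    df$ocean[first_day] == 1L
  sal <- array(NA_real_, c(nlat, nlon, 7L, nt))
  temp <- array(NA_real_, c(nlat, nlon, 7L, nt))
  for (l in 1:7) {
    sal[cbind(ix[, 1:2], l, ix[, 3])] <- df[[paste0("sal_", l)]]
    temp[cbind(ix[, 1:2], l, ix[, 3])] <- df[[paste0("temp_", l)]]
  }
  tmeta <- df[!duplicated(df$itime), c("itime", "year", "day")]
  tmeta <- tmeta[order(tmeta$itime), ]
  g <- ocean_grid(lat, lon, tmeta$year, tmeta$day, ocean,
                  grab3("ssh"), grab3("sss"), grab3("sst"), sal, temp,
                  chla = if ("chla" %in% names(df)) grab3("chla"),
                  chla_true = if ("chla_true" %in% names(df))
                    grab3("chla_true"))
  if ("chla_pred" %in% names(df)) g$chla_pred <- grab3("chla_pred")
  if ("chla_filled" %in% names(df)) g$chla_filled <- grab3("chla_filled")
  if ("provenance" %in% names(df)) {
    a <- array(NA_character_, d3); a[ix] <- df$provenance
    g$provenance <- a
  }
  g
}

#' Build, validate and serialize an experiment configuration
#'
#' A fully serializable description of a gap-filling run: architecture,
#' ensemble size, seeds, split mode, day-of-year denominator, chlorophyll-a
#' threshold and training options, so that identical configurations
#' reproduce identical outputs.
#'
#' @param arch integer vector `c(n_inputs, n_hidden, n_outputs)`.
#' @param n_members ensemble size.
#' @param base_seed integer seed.
#' @param day_denominator 366 or 365.
#' @param threshold chlorophyll-a filter threshold (mg/m3).
#' @param split `"alternating"` or `"by-year"`.
#' @param train_years,validation_years used when `split = "by-year"`.
#' @param training named list overriding [training_options()] fields.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(arch = c(23L, 30L, 1L), n_members = 6L,
                              base_seed = 1L, day_denominator = 366,
                              threshold = 1.0, split = "alternating",
                              train_years = NULL, validation_years = NULL,
                              training = list()) {
  stopifnot(length(arch) == 3L, all(arch >= 1L),
            day_denominator %in% c(365, 366), threshold > 0,
            split %in% c("alternating", "by-year"))
  n_members <- stopifnot_scalar_int(n_members, "n_members", min = 1)
  base_seed <- stopifnot_scalar_int(base_seed, "base_seed")
  if (split == "by-year" &&
      (is.null(train_years) || is.null(validation_years))) {
    stop("by-year split requires train_years and validation_years",
         call. = FALSE)
  }
  opts <- do.call(training_options, training)
  structure(list(arch = as.integer(arch), n_members = n_members,
                 base_seed = base_seed, day_denominator = day_denominator,
                 threshold = threshold, split = split,
                 train_years = train_years,
                 validation_years = validation_years,
                 training = unclass(opts)),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path file path for the JSON form.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname experiment_config
#' @param config an `experiment_config` (for `write_config`).
#' @export
read_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(arch = obj$arch, n_members = obj$n_members,
                    base_seed = obj$base_seed,
                    day_denominator = obj$day_denominator,
                    threshold = obj$threshold, split = obj$split,
                    train_years = obj$train_years,
                    validation_years = obj$validation_years,
                    training = obj$training[
                      !vapply(obj$training, is.null, logical(1))])
}
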