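# CSV / GeoJSON readers and writers. All tabular artifacts are plain CSV with
# a header and a stable column order, keyed by unit_id so they join across
# stages.

#' Column mapping for tabular input
#'
#' @param id,x,y,population,outcome Column names in the input file.
#' @param covariates Character vector of covariate column names.
#' @return A `column_map` list.
#' @export
column_map <- function(id = "unit_id", x = "x", y = "y",
                       population = "population", outcome = "y_outcome",
                       covariates) {
  if (missing(covariates) || length(covariates) < 1L) {
    config_error("column_map(): at least one covariate column is required")
  }
  structure(list(id = id, x = x, y = y, population = population,
                 outcome = outcome, covariates = covariates),
            class = "column_map")
}

#' Read a unit-level table into a spatial dataset
#'
#' Reads a CSV (or GeoJSON point collection), validates the mapped columns,
#' and standardizes outcome and covariates. Longitude/latitude-named
#' coordinates (or geographic GeoJSON) switch the distance metric to
#' haversine with a notice.
#'
#' @param path CSV or GeoJSON file path.
#' @param map A [column_map()].
#' @param metric `NULL` to infer (`"haversine"` iff the coordinate columns
#'   are named lon/lat-like or the input is GeoJSON), else `"euclidean"` or
#'   `"haversine"`.
#' @return A [spatial_dataset()].
#' @export
read_dataset <- function(path, map, metric = NULL) {
  stopifnot(inherits(map, "column_map"))
  is_geojson <- grepl("\\.(geojson|json)$", path, ignore.case = TRUE)
  if (is_geojson) {
    df <- read_geojson_points(path)
    if (is.null(metric)) {
      metric <- "haversine"
      message("read_dataset(): GeoJSON input; distance metric set to haversine")
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  need <- c(map$id, map$x, map$y, map$population, map$outcome, map$covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) data_error("read_dataset(): missing column(s): %s",
                               paste(miss, collapse = ", "))
  na_rows <- which(rowSums(is.na(df[, need, drop = FALSE])) > 0)
  if (length(na_rows)) {
    data_error("read_dataset(): missing values in mapped columns at row(s) %s",
               paste(utils::head(na_rows, 10), collapse = ", "))
  }
  if (is.null(metric)) {
    lonlat <- grepl("^(lon|lng|longitude)$", map$x, ignore.case = TRUE) &&
      grepl("^(lat|latitude)$", map$y, ignore.case = TRUE)
    metric <- if (lonlat) "haversine" else "euclidean"
    if (lonlat) message("read_dataset(): lon/lat columns; distance metric set to haversine")
  }
  units <- data.frame(unit_id = as.character(df[[map$id]]),
                      x = df[[map$x]], y = df[[map$y]],
                      population = df[[map$population]],
                      stringsAsFactors = FALSE)
  covs <- as.matrix(df[, map$covariates, drop = FALSE])
  spatial_dataset(units, df[[map$outcome]], covs, metric = metric)
}

#' Write a spatial dataset back to CSV on the raw scale
#'
#' Columns: `unit_id, x, y, population, y_outcome, <covariates...>`, with
#' outcome and covariates back-transformed to their original scale.
#'
#' @param data A [spatial_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "spatial_dataset"))
  sc <- data$scaling
  covs <- sweep(sweep(data$X[, -1, drop = FALSE], 2, sc$x_scale, "*"),
                2, sc$x_center, "+")
  df <- data.frame(data$units,
                   y_outcome = data$y * sc$y_scale + sc$y_center,
                   covs, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the true coefficient surfaces of a synthetic dataset
#'
#' @param truth A `truth_bundle` from [simulate_dataset()].
#' @param data The matching [spatial_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, data, path) {
  stopifnot(inherits(truth, "truth_bundle"))
  df <- data.frame(unit_id = data$units$unit_id, truth$beta,
                   noise = truth$noise, check.names = FALSE)
  names(df)[2:(1 + ncol(truth$beta))] <- paste0("beta_", colnames(truth$beta))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) data_error("read_geojson_points(): no features in '%s'", path)
  rows <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      data_error("read_geojson_points(): only Point geometries are supported")
    }
    c(list(x = f$geometry$coordinates[[1]], y = f$geometry$coordinates[[2]]),
      f$properties)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Export per-unit values as a GeoJSON point collection
#'
#' @param data A [spatial_dataset()].
#' @param values Data frame of per-unit properties (recycled column-wise),
#'   or `NULL` for coordinates and population only.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(data, values = NULL, path) {
  stopifnot(inherits(data, "spatial_dataset"))
  u <- data$units
  props <- data.frame(unit_id = u$unit_id, population = u$population,
                      stringsAsFactors = FALSE)
  if (!is.null(values)) props <- cbind(props, values)
  feats <- lapply(seq_len(nrow(u)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(u$x[i], u$y[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Descriptive statistics table (raw scale)
#'
#' Mean, SD, min and max of the outcome and each covariate on their original
#' scales.
#'
#' @param data A [spatial_dataset()].
#' @return Data frame with one row per variable.
#' @export
descriptive_table <- function(data) {
  stopifnot(inherits(data, "spatial_dataset"))
  sc <- data$scaling
  raw <- cbind(y_outcome = data$y * sc$y_scale + sc$y_center,
               sweep(sweep(data$X[, -1, drop = FALSE], 2, sc$x_scale, "*"),
                     2, sc$x_center, "+"))
  data.frame(variable = colnames(raw),
             mean = apply(raw, 2, mean), sd = apply(raw, 2, stats::sd),
             min = apply(raw, 2, min), max = apply(raw, 2, max),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quintile (or other quantile) bins of a numeric vector
#'
#' Sample-quantile bins with ties assigned to the lower bin, for
#' choropleth-style descriptive exports.
#'
#' @param v Numeric vector.
#' @param n_bins Number of bins (default 5).
#' @return Integer bin index in `1..n_bins`.
#' @export
quantile_bins <- function(v, n_bins = 5L) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
  findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
}
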