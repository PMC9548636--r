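# SpatialDataset: the container every fitting stage consumes.
#
# Units are point-referenced observations (county centroids in the motivating
# application) with a population weight (e.g. beneficiary count). The outcome
# and all covariates are stored z-scored -- local and global estimates are
# reported on the standardized scale so coefficient magnitudes are comparable
# across variables and across units -- and the centering/scaling constants are
# retained so raw values can be written back out.

#' Assemble a spatial dataset for (M)GWR fitting
#'
#' Bundles a unit table (ids, coordinates, populations), an outcome vector and
#' a covariate matrix into the container used by [fit_ols()], [fit_gwr()] and
#' [fit_mgwr()]. Outcome and covariates are standardized (mean 0, sample SD 1)
#' and an intercept column is attached to the design matrix; the original
#' centers and scales are kept in `$scaling`.
#'
#' @param units Data frame with columns `unit_id`, `x`, `y`, `population`.
#'   Coordinates are planar unless `metric = "haversine"`, in which case
#'   `x` is longitude and `y` latitude in decimal degrees.
#' @param outcome Numeric outcome vector, one value per unit (raw scale).
#' @param covariates Numeric matrix or data frame of covariates (raw scale),
#'   one row per unit; column names become variable labels.
#' @param metric Distance metric, `"euclidean"` (planar units) or
#'   `"haversine"` (km from lon/lat degrees).
#' @return An object of class `spatial_dataset` with elements `units`, `y`
#'   (standardized outcome), `X` (design matrix including intercept), `names`,
#'   `metric` and `scaling`.
#' @seealso [simulate_dataset()] to generate synthetic instances.
#' @export
spatial_dataset <- function(units, outcome, covariates,
                            metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  units <- validate_units(units)
  n <- nrow(units)
  outcome <- as.numeric(outcome)
  if (length(outcome) != n) data_error("outcome length (%d) != number of units (%d)",
                                       length(outcome), n)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n) data_error("covariate rows != number of units")
  if (ncol(covariates) < 1L) data_error("at least one covariate is required")
  if (anyNA(outcome) || anyNA(covariates)) data_error("missing values in outcome/covariates")
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }

  x_center <- colMeans(covariates)
  x_scale <- apply(covariates, 2, stats::sd)
  bad <- which(x_scale == 0)
  if (length(bad)) {
    degenerate_error("constant covariate column(s): %s",
                     paste(colnames(covariates)[bad], collapse = ", "))
  }
  Xs <- sweep(sweep(covariates, 2, x_center, "-"), 2, x_scale, "/")

  y_center <- mean(outcome)
  y_scale <- stats::sd(outcome)
  if (y_scale == 0) degenerate_error("outcome is constant")
  y <- (outcome - y_center) / y_scale

  X <- cbind("(Intercept)" = 1, Xs)
  structure(list(
    units = units,
    y = y,
    X = X,
    names = colnames(X),
    metric = metric,
    scaling = list(y_center = y_center, y_scale = y_scale,
                   x_center = x_center, x_scale = x_scale)
  ), class = "spatial_dataset")
}

validate_units <- function(units) {
  units <- as.data.frame(units)
  need <- c("unit_id", "x", "y", "population")
  miss <- setdiff(need, names(units))
  if (length(miss)) data_error("unit table lacks column(s): %s", paste(miss, collapse = ", "))
  units$unit_id <- as.character(units$unit_id)
  if (anyDuplicated(units$unit_id)) data_error("duplicate unit_id values")
  if (anyDuplicated(units[, c("x", "y")])) data_error("duplicated coordinate pairs")
  if (any(!is.finite(units$x)) || any(!is.finite(units$y))) data_error("non-finite coordinates")
  if (any(units$population < 1)) data_error("populations must be >= 1")
  units[, need]
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d units, %d covariates (+ intercept), metric = %s\n",
              nrow(x$units), ncol(x$X) - 1L, x$metric))
  cat("  covariates:", paste(x$names[-1], collapse = ", "), "\n")
  invisible(x)
}

n_units <- function(data) nrow(data$units)

#' Pairwise inter-unit distance matrix
#'
#' @param units Unit data frame (`unit_id`, `x`, `y`, `population`) or a
#'   `spatial_dataset` (its metric is then used unless overridden).
#' @param metric `"euclidean"` for planar coordinates; `"haversine"` for
#'   great-circle distances in kilometres from lon/lat degrees.
#' @return Symmetric n x n matrix with a zero diagonal.
#' @export
distance_matrix <- function(units, metric = c("euclidean", "haversine")) {
  if (inherits(units, "spatial_dataset")) {
    if (missing(metric)) metric <- units$metric
    units <- units$units
  }
  metric <- match.arg(metric)
  xy <- cbind(units$x, units$y)
  if (any(!is.finite(xy))) data_error("non-finite coordinates")
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(xy))
  } else {
    if (any(abs(units$x) > 180) || any(abs(units$y) > 90)) {
      config_error("haversine metric requires lon in [-180,180], lat in [-90,90]")
    }
    D <- geosphere::distm(xy, fun = geosphere::distHaversine) / 1000
  }
  dimnames(D) <- NULL
  diag(D) <- 0
  D
}
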