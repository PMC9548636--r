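# Composite covariate construction: first-principal-component indices
# (social isolation, concentrated disadvantage) and mean-of-z indices
# (residential stability). PCA is done on the correlation matrix: inputs mix
# percentages and logged dollars, and loadings are only comparable across
# variables after column standardization.

#' Define a composite index
#'
#' @param name Index label.
#' @param inputs Character vector (>= 2) of input variable names.
#' @param method `"pca-first-component"` or `"mean-of-z"`.
#' @param anchor Name of one input whose loading/contribution must come out
#'   positive; fixes the sign of the PCA score semantically (e.g. a poverty
#'   share anchors a deprivation index so that higher = more deprived).
#' @return An `index_spec` object.
#' @export
index_spec <- function(name, inputs, method = c("pca-first-component", "mean-of-z"),
                       anchor = inputs[1]) {
  method <- match.arg(method)
  if (length(inputs) < 2L) config_error("index_spec(): need >= 2 input variables")
  if (!anchor %in% inputs) config_error("index_spec(): anchor '%s' is not among the inputs", anchor)
  structure(list(name = name, inputs = inputs, method = method, anchor = anchor),
            class = "index_spec")
}

#' First-principal-component composite index
#'
#' Column-standardizes the inputs, extracts the first principal component of
#' the resulting correlation structure, and orients it so the anchor
#' variable's loading is positive. Loadings are reported as correlations
#' between each (standardized) input and the score vector, and
#' `variance_explained` is the leading eigenvalue's share of total variance.
#'
#' @param X Numeric unit x variable matrix or data frame (>= 3 rows, no
#'   missing values); columns must cover `spec$inputs`.
#' @param spec An [index_spec()] with method `"pca-first-component"`.
#' @return An `index_result`: `scores` (mean 0), `loadings`,
#'   `variance_explained`, `method`, `name`.
#' @export
pca_index <- function(X, spec) {
  if (!inherits(spec, "index_spec")) config_error("pca_index(): not an index_spec")
  if (spec$method != "pca-first-component") config_error("pca_index(): spec method is '%s'", spec$method)
  Xs <- prepare_index_matrix(X, spec$inputs, min_rows = 3L)
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  v <- pr$rotation[, 1]
  scores <- as.vector(Xs %*% v)
  if (stats::sd(scores) == 0) degenerate_error("pca_index(): degenerate leading component")
  loadings <- as.vector(suppressWarnings(stats::cor(Xs, scores)))
  names(loadings) <- colnames(Xs)
  if (loadings[spec$anchor] < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  ve <- pr$sdev[1]^2 / sum(pr$sdev^2)
  structure(list(name = spec$name, scores = scores, loadings = loadings,
                 variance_explained = ve, method = spec$method),
            class = "index_result")
}

#' Mean-of-standardized-variables index
#'
#' Row-wise mean of column-standardized inputs (the residential-stability
#' construction).
#'
#' @param X Numeric unit x variable matrix or data frame with >= 2
#'   non-constant columns.
#' @return Numeric score vector, one per row.
#' @export
mean_index <- function(X) {
  Xs <- prepare_index_matrix(X, inputs = NULL, min_rows = 2L)
  if (ncol(Xs) < 2L) config_error("mean_index(): need >= 2 columns")
  rowMeans(Xs)
}

prepare_index_matrix <- function(X, inputs = NULL, min_rows = 3L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.null(inputs) && length(inputs)) {
    miss <- setdiff(inputs, colnames(X))
    if (length(miss)) data_error("missing input column(s): %s", paste(miss, collapse = ", "))
    X <- X[, inputs, drop = FALSE]
  }
  if (nrow(X) < min_rows) data_error("need >= %d rows", min_rows)
  if (anyNA(X)) data_error("missing values in index inputs")
  apply(X, 2, standardize)
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<index_result> %s (%s)\n  variance explained: %.1f%%\n",
              x$name, x$method, 100 * x$variance_explained))
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}
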