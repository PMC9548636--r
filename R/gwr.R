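# Geographically weighted regression with an adaptive bisquare kernel.
#
# At each unit i a weighted least-squares fit is calibrated,
#   beta_hat_i = (X' W_i X)^{-1} X' W_i y,
# with W_i diagonal and built from the bisquare kernel truncated at the
# distance to the k-th nearest unit (self included, self-distance 0, weight 1).
# The i-th hat-matrix row is x_i' (X' W_i X)^{-1} X' W_i; its trace drives the
# AICc used for bandwidth selection.

#' Adaptive-bisquare kernel specification
#'
#' @param k_neighbors Integer bandwidth: number of nearest units (self
#'   included) receiving nonzero weight.
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(k_neighbors) {
  if (!is.numeric(k_neighbors) || k_neighbors < 2) {
    config_error("kernel_spec(): k_neighbors must be an integer >= 2")
  }
  structure(list(kind = "adaptive-bisquare", k_neighbors = as.integer(k_neighbors)),
            class = "kernel_spec")
}

#' Adaptive bisquare weights for one calibration location
#'
#' The truncation distance `b` is the distance to the `k`-th nearest unit
#' (self included as nearest, at distance 0); weights are
#' `(1 - (d/b)^2)^2` for `d < b` and exactly 0 at or beyond `b` (the kernel
#' support is open at `b`, so units tied at the k-th distance get weight 0).
#'
#' @param dist_row Distances from the calibration location to every unit.
#' @param k_neighbors Integer bandwidth, `2 <= k_neighbors <= length(dist_row)`.
#' @return Weight vector in `[0, 1]`.
#' @export
adaptive_bisquare <- function(dist_row, k_neighbors) {
  if (k_neighbors < 2) config_error("adaptive_bisquare(): k_neighbors must be >= 2")
  if (k_neighbors > length(dist_row)) {
    config_error("adaptive_bisquare(): k_neighbors (%d) exceeds number of units (%d)",
                 k_neighbors, length(dist_row))
  }
  b <- sort(dist_row, partial = k_neighbors)[k_neighbors]
  if (b <= 0) degenerate_error("adaptive_bisquare(): bandwidth distance is zero (duplicated coordinates?)")
  u <- dist_row / b
  w <- (1 - u^2)^2
  w[u >= 1] <- 0
  w
}

#' Local weighted least-squares fit (one calibration location)
#'
#' Solves the weighted normal equations
#' `beta_hat = (X'WX)^{-1} X'W y` for one location's weight vector. When a
#' focal row index is supplied, the corresponding hat-matrix row
#' `x_i'(X'WX)^{-1}X'W` and the unscaled coefficient covariance diagonal
#' `diag[(X'WX)^{-1} X'W^2X (X'WX)^{-1}]` are returned too.
#'
#' @param X Design matrix (including intercept column).
#' @param y Outcome vector.
#' @param w Nonnegative weight vector (one per row of `X`).
#' @param focal Optional row index of the calibration unit.
#' @return List with `coefficients`, and when `focal` is given, `leverage`
#'   (hat row) and `cov_unscaled` (multiply by sigma^2 for variances).
#' @export
local_fit <- function(X, y, w, focal = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(w > 0) < p) {
    singularity_error("local_fit(): only %d positive weights for %d parameters",
                      sum(w > 0), p)
  }
  Xw <- X * w
  A <- crossprod(Xw, X)
  R <- tryCatch(chol(A), error = function(e)
    singularity_error("local_fit(): singular local design%s",
                      if (is.null(focal)) "" else sprintf(" at unit %d", focal)))
  beta <- backsolve(R, forwardsolve(t(R), crossprod(Xw, y)))
  out <- list(coefficients = as.vector(beta))
  if (!is.null(focal)) {
    # C = (X'WX)^{-1} X'W  (p x n); hat row = x_i' C; CC' diag gives SEs
    C <- backsolve(R, forwardsolve(t(R), t(Xw)))
    out$leverage <- as.vector(X[focal, ] %*% C)
    out$cov_unscaled <- rowSums(C^2)
  }
  out
}

#' Fit GWR at a single bandwidth
#'
#' Calibrates one local fit per unit, assembles the hat matrix, and computes
#' local standard errors (`sigma2 = RSS / (n - tr(S))`), AICc, and local R^2
#' (weighted by each unit's own kernel).
#'
#' @param data A [spatial_dataset()].
#' @param kernel A [kernel_spec()]; `k_neighbors` must be at least the number
#'   of model terms + 1 and at most n.
#' @param D Optional precomputed distance matrix.
#' @return A `gwr_result`: `coefficients` (n x (k+1)), `se`, `t`, `fitted`,
#'   `residuals`, `rss`, `trace_s`, `hat` (n x n smoother), `aicc`,
#'   `bandwidth`, `local_r2`, `names`.
#' @export
fit_gwr <- function(data, kernel, D = NULL) {
  stopifnot(inherits(data, "spatial_dataset"))
  if (!inherits(kernel, "kernel_spec")) kernel <- kernel_spec(kernel)
  X <- data$X; y <- data$y
  n <- nrow(X); p <- ncol(X)
  k <- kernel$k_neighbors
  if (k < p + 1L) config_error("fit_gwr(): k_neighbors (%d) below k + 2 = %d", k, p + 1L)
  if (k > n) config_error("fit_gwr(): k_neighbors (%d) exceeds n (%d)", k, n)
  if (is.null(D)) D <- distance_matrix(data)

  beta <- matrix(NA_real_, n, p, dimnames = list(data$units$unit_id, data$names))
  cov_unscaled <- matrix(NA_real_, n, p)
  S <- matrix(NA_real_, n, n)
  local_r2 <- numeric(n)
  for (i in seq_len(n)) {
    w <- adaptive_bisquare(D[i, ], k)
    lf <- withCallingHandlers(
      local_fit(X, y, w, focal = i),
      mgwrdim_singularity_error = function(e) {
        singularity_error("fit_gwr(): singular local design at unit '%s' (bandwidth %d)",
                          data$units$unit_id[i], k)
      })
    beta[i, ] <- lf$coefficients
    cov_unscaled[i, ] <- lf$cov_unscaled
    S[i, ] <- lf$leverage
    e_loc <- y - as.vector(X %*% lf$coefficients)
    ybar_w <- sum(w * y) / sum(w)
    local_r2[i] <- 1 - sum(w * e_loc^2) / sum(w * (y - ybar_w)^2)
  }
  fitted <- rowSums(X * beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  trace_s <- sum(diag(S))
  sigma2 <- rss / (n - trace_s)
  se <- sqrt(sigma2 * cov_unscaled)
  dimnames(se) <- dimnames(beta)
  structure(list(
    coefficients = beta, se = se, t = beta / se,
    fitted = fitted, residuals = resid, rss = rss,
    trace_s = trace_s, hat = S,
    aicc = model_aicc(rss, n, trace_s),
    bandwidth = k, local_r2 = local_r2, names = data$names, n = n
  ), class = "gwr_result")
}

#' @export
print.gwr_result <- function(x, ...) {
  cat(sprintf("<gwr_result> n = %d, bandwidth = %d neighbors, tr(S) = %.1f, AICc = %.2f\n",
              x$n, x$bandwidth, x$trace_s, x$aicc))
  cat("  local estimate summary:\n")
  print(round(t(apply(x$coefficients, 2, summary)), 3))
  invisible(x)
}

# AICc profile point for bandwidth search: coefficients + hat diagonal only.
gwr_bandwidth_score <- function(D, X, y, bw) {
  n <- nrow(X)
  rss <- 0
  tr <- 0
  for (i in seq_len(n)) {
    w <- adaptive_bisquare(D[i, ], bw)
    Xw <- X * w
    A <- crossprod(Xw, X)
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    beta <- backsolve(R, forwardsolve(t(R), crossprod(Xw, y)))
    xi <- X[i, ]
    # self weight is 1 (d = 0), so s_ii = x_i' A^{-1} x_i
    z <- forwardsolve(t(R), xi)
    tr <- tr + sum(z^2)
    rss <- rss + (y[i] - sum(xi * beta))^2
  }
  if (n - 2 - tr <= 0) return(Inf)
  model_aicc(rss, n, tr)
}

# Integer golden-section minimizer with memoization and exhaustive refinement.
# Small ranges are scanned outright; otherwise golden-section shrinks the
# bracket to <= `window` and that window is scanned. Ties return the smallest
# minimizer among evaluated points.
golden_section_int <- function(f, lo, hi, exhaustive_width = 50L, window = 20L) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo > hi) config_error("bandwidth search range is empty")
  memo <- new.env(hash = TRUE, parent = emptyenv())
  F <- function(b) {
    key <- as.character(b)
    v <- memo[[key]]
    if (is.null(v)) {
      v <- f(b)
      memo[[key]] <- v
    }
    v
  }
  a <- lo; b <- hi
  if (b - a + 1L > exhaustive_width) {
    phi <- (sqrt(5) - 1) / 2
    x1 <- as.integer(round(b - phi * (b - a)))
    x2 <- as.integer(round(a + phi * (b - a)))
    while (b - a > window) {
      if (x1 >= x2) x2 <- x1 + 1L
      if (F(x1) <= F(x2)) b <- x2 else a <- x1
      x1 <- as.integer(round(b - phi * (b - a)))
      x2 <- as.integer(round(a + phi * (b - a)))
    }
  }
  ks <- a:b
  vals <- vapply(ks, F, numeric(1))
  best <- ks[which.min(vals)]
  # report all evaluated points for diagnostics
  ev <- sort(as.integer(ls(memo)))
  attr(best, "profile") <- data.frame(bandwidth = ev,
                                      aicc = vapply(as.character(ev),
                                                    function(k) memo[[k]], numeric(1)))
  best
}

#' AICc-optimal adaptive bandwidth
#'
#' Golden-section search over integer neighbor counts minimizing the GWR
#' AICc, with exhaustive scanning for narrow ranges and a final exhaustive
#' sweep of the converged bracket; ties return the smallest minimizer.
#'
#' @param data A [spatial_dataset()].
#' @param criterion Only `"aicc"`.
#' @param range Integer `c(lo, hi)` within `[k + 2, n]`; defaults to the full
#'   feasible range.
#' @param D Optional precomputed distance matrix.
#' @return Integer bandwidth; attribute `"profile"` holds the evaluated
#'   (bandwidth, AICc) points.
#' @export
select_bandwidth <- function(data, criterion = "aicc", range = NULL, D = NULL) {
  stopifnot(inherits(data, "spatial_dataset"))
  criterion <- match.arg(criterion, "aicc")
  X <- data$X; y <- data$y
  n <- nrow(X)
  lo_min <- ncol(X) + 1L
  if (is.null(range)) range <- c(lo_min, n)
  range <- as.integer(range)
  if (range[1] < lo_min || range[2] > n || range[1] > range[2]) {
    config_error("select_bandwidth(): range must lie within [%d, %d]", lo_min, n)
  }
  if (is.null(D)) D <- distance_matrix(data)
  golden_section_int(function(bw) gwr_bandwidth_score(D, X, y, bw),
                     range[1], range[2])
}
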