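# Global OLS baseline on standardized variables, VIF diagnostics, and the
# hat-trace AICc shared by every model in the pipeline so fit comparisons
# (OLS vs GWR vs MGWR) are internally consistent.

#' Corrected Akaike Information Criterion (hat-trace form)
#'
#' `AICc = 2n log(sigma_hat) + n log(2*pi) + n (n + tr(S)) / (n - 2 - tr(S))`
#' with `sigma_hat^2 = RSS / n`. For OLS the hat trace is the parameter count
#' `k + 1`; for (M)GWR it is the trace of the smoother matrix, so model
#' complexity is measured on one common scale.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of observations.
#' @param trace_s Hat-matrix trace (effective number of parameters).
#' @return The AICc value (scalar).
#' @export
model_aicc <- function(rss, n, trace_s) {
  if (rss <= 0) config_error("model_aicc(): rss must be > 0")
  if (n - 2 - trace_s <= 0) {
    config_error("model_aicc(): oversaturated model (n - 2 - trace_s = %.2f <= 0)",
                 n - 2 - trace_s)
  }
  sigma2 <- rss / n
  n * log(sigma2) + n * log(2 * pi) + n * (n + trace_s) / (n - 2 - trace_s)
}

#' Global OLS fit on standardized data
#'
#' Fits the outcome on all covariates by ordinary least squares via
#' [stats::lm()]. Because the dataset is standardized, coefficients are on
#' the beta (standardized) scale and the intercept is ~0.
#'
#' @param data A [spatial_dataset()].
#' @return An `ols_result`: `coefficients`, `se`, `t`, `p_value`,
#'   `adjusted_r2`, `aicc`, `residuals`, `fitted`, `rss`, `df_residual`.
#' @export
fit_ols <- function(data) {
  stopifnot(inherits(data, "spatial_dataset"))
  X <- data$X
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) config_error("fit_ols(): need n > k + 2 (n = %d, k + 1 = %d)", n, p)
  fit <- stats::lm(data$y ~ X[, -1, drop = FALSE])
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    dropped <- sub("^X\\[, -1, drop = FALSE\\]", "", dropped)
    singularity_error("fit_ols(): singular design; aliased column(s): %s",
                      paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  rownames(co) <- data$names
  rss <- sum(stats::resid(fit)^2)
  structure(list(
    coefficients = co[, 1], se = co[, 2], t = co[, 3], p_value = co[, 4],
    adjusted_r2 = sm$adj.r.squared,
    aicc = model_aicc(rss, n, trace_s = p),
    residuals = as.vector(stats::resid(fit)),
    fitted = as.vector(stats::fitted(fit)),
    rss = rss, df_residual = fit$df.residual, n = n
  ), class = "ols_result")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from regressing covariate `j`
#' on all the others (with intercept). Perfect collinearity yields `Inf`
#' rather than an error, flagged in the result.
#'
#' @param X Covariate matrix (no intercept column), each column non-constant.
#' @return A `vif_report`: named `vif` vector and logical `flagged`
#'   (non-finite or > 10, the conventional collinearity alarm).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) config_error("vif(): need >= 2 covariates")
  if (any(apply(X, 2, stats::sd) == 0)) degenerate_error("vif(): constant column")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  v <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(v) <- colnames(X)
  structure(list(vif = v, flagged = !is.finite(v) | v > 10), class = "vif_report")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("<ols_result> n = %d, adj. R^2 = %.3f, AICc = %.2f\n",
              x$n, x$adjusted_r2, x$aicc))
  tab <- cbind(estimate = x$coefficients, se = x$se, t = x$t, p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' @export
print.vif_report <- function(x, ...) {
  cat("<vif_report>\n")
  print(round(x$vif, 3))
  if (any(x$flagged)) cat("  flagged (VIF > 10 or infinite):",
                          paste(names(x$vif)[x$flagged], collapse = ", "), "\n")
  invisible(x)
}

#' Tidy Table of global estimates and diagnostics
#'
#' @param ols An `ols_result`.
#' @param vif_report Optional `vif_report` for the same covariates.
#' @return Data frame with one row per model term.
#' @export
ols_table <- function(ols, vif_report = NULL) {
  out <- data.frame(variable = names(ols$coefficients),
                    estimate = unname(ols$coefficients),
                    se = unname(ols$se), t = unname(ols$t),
                    p_value = unname(ols$p_value),
                    stringsAsFactors = FALSE)
  out$vif <- NA_real_
  if (!is.null(vif_report)) {
    m <- match(out$variable, names(vif_report$vif))
    out$vif[!is.na(m)] <- vif_report$vif[m[!is.na(m)]]
  }
  out
}
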