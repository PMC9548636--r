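# Multiscale GWR via back-fitting.
#
# The model is additive, y = sum_j f_j + eps, each term f_j = beta_j(u) x_j a
# spatial coefficient surface smoothed at its own bandwidth. Back-fitting
# cycles over terms: form the partial residual e_j = y - sum_{l != j} f_l,
# calibrate a univariate GWR of e_j on x_j (selecting that term's bandwidth
# by AICc), and update f_j. Because each term update is linear in y given the
# bandwidth sequence, per-term hat matrices R_j (f_j = R_j y) can be tracked
# through the iterations; their traces are the per-variable effective numbers
# of parameters (ENP_j), which sum to the total hat trace by construction and
# drive both the AICc and the corrected local t-tests.

#' MGWR fitting options
#'
#' @param tol SOC-f convergence tolerance on successive fitted-value vectors.
#' @param max_iter Maximum back-fitting sweeps.
#' @param search_range Integer `c(lo, hi)` bandwidth search range; default
#'   `[k + 3, n]` (univariate terms need few neighbors, but very small
#'   bandwidths are numerically fragile).
#' @param alpha Nominal two-sided level for local inference.
#' @param hat Track per-term hat matrices (needed for ENP, SEs, AICc and the
#'   corrected critical t). Disable for speed when only coefficients and
#'   bandwidths are needed (e.g. inside the Monte Carlo test).
#' @param n_final_sweeps Extra sweeps run with bandwidths frozen after SOC
#'   convergence, stabilizing the term decomposition.
#' @param verbose Print per-sweep SOC values.
#' @return An `mgwr_options` list.
#' @export
mgwr_options <- function(tol = 1e-5, max_iter = 200L, search_range = NULL,
                         alpha = 0.05, hat = TRUE, n_final_sweeps = 2L,
                         verbose = FALSE) {
  if (tol <= 0) config_error("mgwr_options(): tol must be > 0")
  if (max_iter < 1) config_error("mgwr_options(): max_iter must be >= 1")
  list(tol = tol, max_iter = as.integer(max_iter), search_range = search_range,
       alpha = alpha, hat = isTRUE(hat),
       n_final_sweeps = as.integer(n_final_sweeps), verbose = isTRUE(verbose))
}

#' Score-of-change convergence criterion
#'
#' `sqrt( mean((curr - prev)^2) / mean(curr^2) )`: the root-mean-square change
#' in the fitted values, normalized by their root-mean-square level. Zero iff
#' the two vectors are identical; falls back to the absolute (unnormalized)
#' form when the current fit is all zero.
#'
#' @param fitted_prev,fitted_curr Equal-length numeric vectors.
#' @return Nonnegative scalar.
#' @export
soc_f <- function(fitted_prev, fitted_curr) {
  if (length(fitted_prev) != length(fitted_curr)) {
    config_error("soc_f(): length mismatch")
  }
  num <- mean((fitted_curr - fitted_prev)^2)
  den <- mean(fitted_curr^2)
  if (den == 0) return(sqrt(num))
  sqrt(num / den)
}

#' Corrected critical t for dependent local tests
#'
#' Local estimates at nearby units are dependent; treating each of the
#' ENP_j effective tests as independent, the familywise level alpha is spread
#' as `alpha_j = alpha / ENP_j` and the two-sided critical value is
#' `qt(1 - alpha_j / 2, df)`.
#'
#' @param alpha Nominal familywise level in (0, 0.5].
#' @param enp_j Effective number of parameters for the variable (>= 1;
#'   values below 1 are clipped to 1 with a warning).
#' @param df Residual degrees of freedom (`n - tr(S)`).
#' @return Positive critical t value.
#' @export
corrected_critical_t <- function(alpha, enp_j, df) {
  if (alpha <= 0 || alpha > 0.5) config_error("corrected_critical_t(): alpha must be in (0, 0.5]")
  if (enp_j < 1) {
    warning("corrected_critical_t(): enp_j < 1 clipped to 1")
    enp_j <- 1
  }
  stats::qt(1 - (alpha / enp_j) / 2, df = df)
}

# ---- internal machinery ----------------------------------------------------

# Row-sorted distance matrix: column i holds sort(D[i, ]), so the k-th
# nearest distance for every unit is Dsort[k, ].
row_sorted_distances <- function(D) apply(D, 1, sort)

# Dense bisquare weight matrix at one adaptive bandwidth. b recycles down
# columns, i.e. row-wise: W[i, j] uses unit i's truncation distance.
bisquare_weight_matrix <- function(D, Dsort, bw) {
  b <- Dsort[bw, ]
  if (any(b <= 0)) degenerate_error("zero kernel bandwidth (duplicated coordinates?)")
  U <- D / b
  W <- (1 - U^2)^2
  W[U >= 1] <- 0
  W
}

make_weight_cache <- function(D, Dsort, max_entries = 80L) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(bw) {
    key <- as.character(bw)
    W <- cache[[key]]
    if (is.null(W)) {
      W <- bisquare_weight_matrix(D, Dsort, bw)
      if (length(ls(cache)) < max_entries) cache[[key]] <- W
    }
    W
  }
}

# Univariate GWR of e on xj with weight matrix W: closed form
# beta_i = sum_m w_im x_m e_m / sum_m w_im x_m^2, vectorized over units.
term_smooth <- function(W, xj, e) {
  den <- as.vector(W %*% (xj * xj))
  if (any(den <= 0)) singularity_error("degenerate univariate local design")
  beta <- as.vector(W %*% (xj * e)) / den
  list(beta = beta, f = beta * xj, den = den)
}

# AICc of the univariate GWR of e on xj at bandwidth bw (self weight = 1, so
# the hat diagonal is x_i^2 / den_i).
term_aicc <- function(weights_for, xj, e, bw, n) {
  W <- weights_for(bw)
  ts <- tryCatch(term_smooth(W, xj, e), mgwrdim_singularity_error = function(err) NULL)
  if (is.null(ts)) return(Inf)
  rss <- sum((e - ts$f)^2)
  tr <- sum(xj^2 / ts$den)
  if (rss <= 0 || n - 2 - tr <= 0) return(Inf)
  model_aicc(rss, n, tr)
}

# Full hat-matrix S_j of the univariate smoother: S_j[i, m] = x_i W[i,m] x_m / den_i.
term_smoother_matrix <- function(W, xj, den) {
  (xj / den) * sweep(W, 2, xj, "*")
}

# Core back-fitting loop shared by fit_mgwr() and the Monte Carlo test.
# If `bandwidths` is NULL they are re-selected each sweep until SOC < tol,
# then frozen for `n_final_sweeps` extra sweeps; otherwise they stay fixed.
# `weights_for` maps a bandwidth to its dense weight matrix.
mgwr_backfit <- function(X, y, weights_for, opts, bandwidths = NULL,
                         search_range, track_hat = FALSE) {
  n <- nrow(X); p <- ncol(X)
  select <- is.null(bandwidths)
  if (select) bandwidths <- rep(NA_integer_, p)

  # Initialize additive terms from the global OLS fit (its all-global limit
  # is then a back-fitting fixed point).
  A <- chol2inv(chol(crossprod(X)))
  H <- A %*% t(X)                       # p x n
  beta_ols <- as.vector(H %*% y)
  Fmat <- sweep(X, 2, beta_ols, "*")    # term fits f_j
  beta <- matrix(rep(beta_ols, each = n), n, p)
  Rj <- NULL; Rsum <- NULL
  if (track_hat) {
    Rj <- lapply(seq_len(p), function(j) outer(X[, j], H[j, ]))
    Rsum <- Reduce(`+`, Rj)
  }
  fitted <- rowSums(Fmat)
  soc_trace <- numeric(0)
  rss_trace <- numeric(0)
  frozen <- !select
  final_left <- if (select) -1L else 0L
  converged <- FALSE
  iter <- 0L

  while (iter < opts$max_iter) {
    iter <- iter + 1L
    fitted_prev <- fitted
    for (j in seq_len(p)) {
      ej <- y - fitted + Fmat[, j]
      xj <- X[, j]
      if (select && !frozen) {
        bandwidths[j] <- as.integer(golden_section_int(
          function(bw) term_aicc(weights_for, xj, ej, bw, n),
          search_range[1], search_range[2]))
      }
      W <- weights_for(bandwidths[j])
      ts <- term_smooth(W, xj, ej)
      if (track_hat) {
        Sj <- term_smoother_matrix(W, xj, ts$den)
        Ej <- diag(n) - Rsum + Rj[[j]]
        Rj_new <- Sj %*% Ej
        Rsum <- Rsum - Rj[[j]] + Rj_new
        Rj[[j]] <- Rj_new
      }
      fitted <- fitted - Fmat[, j] + ts$f
      Fmat[, j] <- ts$f
      beta[, j] <- ts$beta
    }
    soc <- soc_f(fitted_prev, fitted)
    soc_trace <- c(soc_trace, soc)
    if (frozen) rss_trace <- c(rss_trace, sum((y - fitted)^2))
    if (opts$verbose) message(sprintf("  sweep %d: SOC-f = %.3g", iter, soc))
    if (final_left > 0L) {
      final_left <- final_left - 1L
      if (final_left == 0L) { converged <- TRUE; break }
    } else if (soc < opts$tol) {
      if (!frozen && opts$n_final_sweeps > 0L) {
        frozen <- TRUE
        final_left <- opts$n_final_sweeps
      } else {
        converged <- TRUE
        break
      }
    }
  }
  list(beta = beta, bandwidths = as.integer(bandwidths), Fmat = Fmat,
       fitted = fitted, Rj = Rj, Rsum = Rsum, soc_trace = soc_trace,
       rss_trace = rss_trace, iterations = iter, converged = converged)
}

#' Fit a multiscale GWR by back-fitting
#'
#' Calibrates the additive model `y = sum_j f_j + eps` with a per-term
#' adaptive-bisquare bandwidth chosen by AICc within each sweep; after SOC-f
#' convergence the bandwidths are frozen for `n_final_sweeps` stabilizing
#' sweeps. With `hat = TRUE` (default) per-term hat matrices give ENP_j,
#' local standard errors, total-model AICc and corrected critical t values.
#'
#' @param data A [spatial_dataset()] (standardized by construction).
#' @param opts An [mgwr_options()] list.
#' @param D Optional precomputed distance matrix.
#' @return An `mgwr_result`: `bandwidths` (per term, intercept included),
#'   `coefficients` (n x (k+1)), `se`, `t`, `enp`, `trace_s`, `aicc`, `rss`,
#'   `fitted`, `residuals`, `soc_trace`, `rss_trace`, `crit_t` (per variable,
#'   level `opts$alpha` corrected by ENP_j), `converged`, `iterations`.
#' @export
fit_mgwr <- function(data, opts = mgwr_options(), D = NULL) {
  stopifnot(inherits(data, "spatial_dataset"))
  X <- data$X; y <- data$y
  n <- nrow(X); p <- ncol(X)
  if (n <= 3 * p) config_error("fit_mgwr(): need n > 3 (k + 1); n = %d, k + 1 = %d", n, p)
  if (is.null(D)) D <- distance_matrix(data)
  Dsort <- row_sorted_distances(D)
  weights_for <- make_weight_cache(D, Dsort)
  search_range <- opts$search_range %||% c(p + 3L, n)
  search_range <- as.integer(search_range)
  if (search_range[1] < 3L || search_range[2] > n || search_range[1] > search_range[2]) {
    config_error("fit_mgwr(): search_range must lie within [3, %d]", n)
  }

  bf <- mgwr_backfit(X, y, weights_for, opts, bandwidths = NULL,
                     search_range = search_range, track_hat = opts$hat)
  if (!bf$converged) {
    warning(sprintf("fit_mgwr(): back-fitting did not converge in %d sweeps (last SOC-f = %.3g)",
                    bf$iterations, utils::tail(bf$soc_trace, 1)))
  }
  resid <- y - bf$fitted
  rss <- sum(resid^2)
  out <- list(
    bandwidths = stats::setNames(bf$bandwidths, data$names),
    coefficients = structure(bf$beta, dimnames = list(data$units$unit_id, data$names)),
    fitted = bf$fitted, residuals = resid, rss = rss,
    soc_trace = bf$soc_trace, rss_trace = bf$rss_trace,
    converged = bf$converged, iterations = bf$iterations,
    names = data$names, n = n, alpha = opts$alpha,
    search_range = search_range
  )
  if (opts$hat) {
    enp <- vapply(bf$Rj, function(M) sum(diag(M)), numeric(1))
    trace_s <- sum(diag(bf$Rsum))
    sigma2 <- rss / (n - trace_s)
    se <- matrix(NA_real_, n, p, dimnames = dimnames(out$coefficients))
    for (j in seq_len(p)) {
      Cj <- bf$Rj[[j]] / X[, j]   # row i divided by x_ij
      se[, j] <- sqrt(sigma2 * rowSums(Cj^2))
    }
    df <- n - trace_s
    out$enp <- stats::setNames(enp, data$names)
    out$trace_s <- trace_s
    out$aicc <- model_aicc(rss, n, trace_s)
    out$se <- se
    out$t <- out$coefficients / se
    out$df_residual <- df
    out$crit_t <- stats::setNames(
      vapply(enp, function(e) corrected_critical_t(opts$alpha, max(e, 1), df),
             numeric(1)),
      data$names)
  }
  structure(out, class = "mgwr_result")
}

#' @export
print.mgwr_result <- function(x, ...) {
  cat(sprintf("<mgwr_result> n = %d, %d sweeps%s\n", x$n, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  if (!is.null(x$aicc)) {
    cat(sprintf("  tr(S) = %.1f, AICc = %.2f\n", x$trace_s, x$aicc))
  }
  tab <- data.frame(bandwidth = x$bandwidths,
                    mean = colMeans(x$coefficients),
                    sd = apply(x$coefficients, 2, stats::sd),
                    min = apply(x$coefficients, 2, min),
                    max = apply(x$coefficients, 2, max))
  if (!is.null(x$enp)) tab$enp <- round(x$enp, 2)
  print(round(tab, 3))
  invisible(x)
}

#' Per-variable summary table of an MGWR fit
#'
#' Mirrors the usual reporting layout: bandwidth, local-estimate summary
#' statistics, ENP and (if available) Monte Carlo p-values.
#'
#' @param fit An `mgwr_result`.
#' @param mc Optional `monte_carlo_report` for the same fit.
#' @return Data frame, one row per model term.
#' @export
mgwr_table <- function(fit, mc = NULL) {
  stopifnot(inherits(fit, "mgwr_result"))
  B <- fit$coefficients
  out <- data.frame(
    variable = fit$names,
    mean = colMeans(B), sd = apply(B, 2, stats::sd),
    min = apply(B, 2, min), median = apply(B, 2, stats::median),
    max = apply(B, 2, max),
    bandwidth = unname(fit$bandwidths),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(fit$enp)) out$enp <- unname(fit$enp)
  if (!is.null(mc)) out$mc_p_value <- unname(mc$p_value[fit$names])
  out
}
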