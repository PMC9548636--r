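# Monte Carlo test for spatial non-stationarity.
#
# Null hypothesis, per variable: the local coefficient surface is flat, i.e.
# any spatial arrangement of the units is equally likely. The test statistic
# is the variance of the local coefficients across units; its null
# distribution is built by shuffling the coordinates among units (data held
# fixed) and re-calibrating with bandwidths frozen at their fitted values.
# Shuffling coordinates only permutes inter-unit distances, so the kernel
# weight matrices of a permuted dataset are row/column permutations of the
# originals -- they are computed once and re-indexed per draw.

#' Monte Carlo test for spatial non-stationarity of MGWR coefficients
#'
#' @param data The [spatial_dataset()] the model was fitted on.
#' @param fitted The `mgwr_result` from [fit_mgwr()].
#' @param n_perm Number of permutations (>= 19).
#' @param seed Integer seed; the report is deterministic given it.
#' @param tol,max_iter Back-fitting controls for the re-calibrations.
#' @return A `monte_carlo_report`: per-variable `p_value` (add-one estimator,
#'   so `p >= 1/(n_perm + 1)`), `observed` statistic (variance of local
#'   coefficients), `perm_stats` matrix, `n_perm`, `seed`.
#' @export
monte_carlo_test <- function(data, fitted, n_perm = 99L, seed = 1L,
                             tol = 1e-5, max_iter = 50L) {
  stopifnot(inherits(data, "spatial_dataset"), inherits(fitted, "mgwr_result"))
  if (n_perm < 19) config_error("monte_carlo_test(): n_perm must be >= 19")
  n_perm <- as.integer(n_perm)
  X <- data$X; y <- data$y
  n <- nrow(X); p <- ncol(X)
  bw <- unname(fitted$bandwidths)
  D <- distance_matrix(data)
  Dsort <- row_sorted_distances(D)
  Wlist <- lapply(unique(bw), function(b) bisquare_weight_matrix(D, Dsort, b))
  names(Wlist) <- as.character(unique(bw))
  opts <- mgwr_options(tol = tol, max_iter = max_iter, hat = FALSE,
                       n_final_sweeps = 0L)

  observed <- apply(fitted$coefficients, 2, stats::var)
  perm_stats <- matrix(NA_real_, n_perm, p,
                       dimnames = list(NULL, fitted$names))
  set.seed(as.integer(seed))
  for (r in seq_len(n_perm)) {
    perm <- sample.int(n)
    Wp <- lapply(Wlist, function(W) W[perm, perm])
    weights_for <- function(b) Wp[[as.character(b)]]
    bf <- mgwr_backfit(X, y, weights_for, opts, bandwidths = bw,
                       search_range = NULL, track_hat = FALSE)
    perm_stats[r, ] <- apply(bf$beta, 2, stats::var)
  }
  p_value <- (1 + colSums(perm_stats >= rep(observed, each = n_perm))) / (1 + n_perm)
  structure(list(p_value = p_value, observed = observed,
                 perm_stats = perm_stats, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "monte_carlo_report")
}

#' @export
print.monte_carlo_report <- function(x, ...) {
  cat(sprintf("<monte_carlo_report> %d permutations (seed %d)\n", x$n_perm, x$seed))
  print(data.frame(observed_var = signif(x$observed, 4),
                   p_value = round(x$p_value, 4)))
  invisible(x)
}
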