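# Three dimensions of geographic disparity for each covariate:
#  * level of influence -- the population-weighted share of units where the
#    variable's local estimate is significant (> 50% => primary influencer);
#  * scalability -- the fitted bandwidth relative to the number of units
#    (> 75% global, 25-75% regional, < 25% local);
#  * specificity -- within each unit, the covariate with the largest absolute
#    standardized local coefficient (regardless of direction), tallied into
#    dominance counts that always partition the units.

#' Population-weighted level of influence
#'
#' `share_j = 100 * sum(pop_i over significant units) / sum(pop_i)`; a
#' variable is a `"primary"` influencer when its share exceeds 50, else
#' `"secondary"`.
#'
#' @param significant Logical unit x variable matrix of local significance.
#' @param populations Positive population weights, one per unit.
#' @return Data frame: `variable`, `influence_share` (percent),
#'   `influence_class`.
#' @export
level_of_influence <- function(significant, populations) {
  significant <- as.matrix(significant)
  if (!is.logical(significant)) data_error("level_of_influence(): significance mask must be logical")
  if (nrow(significant) != length(populations)) {
    data_error("level_of_influence(): %d mask rows vs %d populations",
               nrow(significant), length(populations))
  }
  if (any(populations <= 0)) config_error("level_of_influence(): populations must be positive")
  total <- sum(populations)
  if (total <= 0) config_error("level_of_influence(): zero total population")
  share <- 100 * colSums(significant * populations) / total
  vars <- colnames(significant) %||% paste0("x", seq_len(ncol(significant)))
  data.frame(variable = vars,
             influence_share = unname(share),
             influence_class = ifelse(share > 50, "primary", "secondary"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Scalability thresholds
#'
#' @param n_units Total number of units (the "global bandwidth").
#' @return Named vector `c(lo = 0.25 * n_units, hi = 0.75 * n_units)`.
#' @export
scalability_thresholds <- function(n_units) {
  c(lo = 0.25 * n_units, hi = 0.75 * n_units)
}

#' Classify a bandwidth as global, regional or local
#'
#' A bandwidth above 75% of the number of units is `"global"`, below 25%
#' `"local"`, and anything in the closed interval between is `"regional"`.
#'
#' @param bandwidth Integer bandwidth(s) in `[1, n_units]`.
#' @param n_units Total number of units.
#' @return Character vector of classes.
#' @export
scalability_class <- function(bandwidth, n_units) {
  if (any(bandwidth < 1 | bandwidth > n_units)) {
    config_error("scalability_class(): bandwidth out of [1, %d]", n_units)
  }
  th <- scalability_thresholds(n_units)
  out <- ifelse(bandwidth > th[["hi"]], "global",
                ifelse(bandwidth < th[["lo"]], "local", "regional"))
  names(out) <- names(bandwidth)
  out
}

#' Flag a reported scalability label that contradicts the rule
#'
#' Returns `TRUE` when the by-the-letter classification of `bandwidth`
#' disagrees with a `reported` label (useful for auditing published tables
#' against the stated thresholds).
#'
#' @param bandwidth Integer bandwidth(s).
#' @param n_units Total number of units.
#' @param reported Reported class label(s): "global", "regional" or "local".
#' @return Logical vector, `TRUE` where the label conflicts with the rule.
#' @export
scalability_conflict <- function(bandwidth, n_units, reported) {
  reported <- tolower(reported)
  bad <- setdiff(reported, c("global", "regional", "local"))
  if (length(bad)) config_error("scalability_conflict(): unknown label(s): %s",
                                paste(bad, collapse = ", "))
  scalability_class(bandwidth, n_units) != reported
}

#' Within-unit dominant covariate (specificity)
#'
#' For each unit, the covariate with the largest `|standardized local
#' coefficient|` regardless of sign. Ties are broken by column order (first
#' wins) and recorded in the `"ties"` attribute.
#'
#' @param local_coeffs Unit x covariate matrix of local coefficients
#'   (intercept excluded).
#' @return List: `dominant` (per-unit label), `counts` and `shares` (percent)
#'   per covariate; counts always sum to the number of units.
#' @export
specificity <- function(local_coeffs) {
  B <- as.matrix(local_coeffs)
  if (ncol(B) < 1L) config_error("specificity(): need >= 1 covariate column")
  if (any(!is.finite(B))) data_error("specificity(): non-finite local coefficients")
  vars <- colnames(B) %||% paste0("x", seq_len(ncol(B)))
  A <- abs(B)
  idx <- max.col(A, ties.method = "first")
  rowmax <- A[cbind(seq_len(nrow(A)), idx)]
  n_ties <- sum(rowSums(A == rowmax) > 1L)
  counts <- tabulate(idx, nbins = ncol(B))
  names(counts) <- vars
  out <- list(dominant = vars[idx], counts = counts,
              shares = 100 * counts / nrow(B))
  attr(out, "ties") <- n_ties
  if (n_ties > 0L) message(sprintf("specificity(): %d tie(s) broken by column order", n_ties))
  out
}

#' Assemble the three-dimension disparity report
#'
#' Builds the per-variable report (influence share/class, scalability class,
#' dominance count/share) and the per-unit dominant-variable table from a
#' fitted MGWR. Significance uses `|t| > critical t`, with the critical value
#' either corrected for dependent tests (`alpha / ENP_j`, the default) or
#' nominal. The intercept is excluded from influence and specificity but
#' listed with its scalability class.
#'
#' @param fit An `mgwr_result` fitted with `hat = TRUE`.
#' @param data The [spatial_dataset()] it was fitted on.
#' @param alpha_policy `"corrected"` (default) or `"nominal"`.
#' @param alpha Two-sided level (default the fit's alpha).
#' @return A `dimension_report`: `$variables` (one row per term) and
#'   `$units` (`unit_id`, `dominant_variable`).
#' @export
dimension_report <- function(fit, data, alpha_policy = c("corrected", "nominal"),
                             alpha = NULL) {
  stopifnot(inherits(fit, "mgwr_result"), inherits(data, "spatial_dataset"))
  if (is.null(fit$se)) config_error("dimension_report(): fit lacks SEs; rerun fit_mgwr() with hat = TRUE")
  alpha_policy <- match.arg(alpha_policy)
  alpha <- alpha %||% fit$alpha
  n <- fit$n
  crit <- if (alpha_policy == "corrected") {
    vapply(pmax(fit$enp, 1), function(e) corrected_critical_t(alpha, e, fit$df_residual),
           numeric(1))
  } else {
    rep(stats::qt(1 - alpha / 2, df = fit$df_residual), length(fit$names))
  }
  sig <- sweep(abs(fit$t), 2, crit, ">")

  cov_idx <- -1L   # drop intercept column
  infl <- level_of_influence(sig[, cov_idx, drop = FALSE], data$units$population)
  spec <- specificity(fit$coefficients[, cov_idx, drop = FALSE])

  vars <- data.frame(
    variable = fit$names,
    bandwidth = unname(fit$bandwidths),
    scalability_class = unname(scalability_class(fit$bandwidths, n)),
    stringsAsFactors = FALSE, row.names = NULL)
  m <- match(vars$variable, infl$variable)
  vars$influence_share <- infl$influence_share[m]
  vars$influence_class <- infl$influence_class[m]
  ms <- match(vars$variable, names(spec$counts))
  vars$dominance_count <- unname(spec$counts[ms])
  vars$dominance_share <- unname(spec$shares[ms])

  structure(list(
    variables = vars,
    units = data.frame(unit_id = data$units$unit_id,
                       dominant_variable = spec$dominant,
                       stringsAsFactors = FALSE),
    alpha = alpha, alpha_policy = alpha_policy
  ), class = "dimension_report")
}

#' @export
print.dimension_report <- function(x, ...) {
  cat(sprintf("<dimension_report> alpha = %.3g (%s)\n", x$alpha, x$alpha_policy))
  tab <- x$variables
  tab$influence_share <- round(tab$influence_share, 1)
  tab$dominance_share <- round(tab$dominance_share, 1)
  print(tab)
  invisible(x)
}
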