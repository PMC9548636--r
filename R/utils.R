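# Shared condition helpers and small numerics.

cond_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mgwrdim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

config_error <- function(msg, ...) cond_stop("mgwrdim_config_error", msg, ...)
data_error <- function(msg, ...) cond_stop("mgwrdim_data_error", msg, ...)
degenerate_error <- function(msg, ...) cond_stop("mgwrdim_degenerate_error", msg, ...)
singularity_error <- function(msg, ...) cond_stop("mgwrdim_singularity_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize a numeric vector to mean zero, sample SD one
#'
#' z-scores a vector using the sample standard deviation (denominator n-1),
#' the convention used throughout the pipeline for outcome, covariates and
#' composite-index inputs.
#'
#' @param v Numeric vector with at least two distinct finite values.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(v) {
  if (!is.numeric(v)) data_error("standardize() requires a numeric vector")
  if (anyNA(v) || any(!is.finite(v))) data_error("standardize(): missing or non-finite values")
  s <- stats::sd(v)
  if (length(unique(v)) < 2L || s == 0) {
    degenerate_error("standardize(): input is constant (zero variance)")
  }
  as.vector((v - mean(v)) / s)
}
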