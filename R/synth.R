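# Synthetic spatial data with known coefficient surfaces.
#
# Downstream stages are validated against data whose true local coefficients
# are known. Each term's surface is one of three archetypes mirroring the
# scales a multiscale model should tell apart: a constant surface (a global,
# stationary association), a planar gradient (a regional, smoothly drifting
# association) and a compact bump (a local association confined to one
# pocket). The outcome is the exact local linear predictor plus i.i.d.
# Gaussian noise: y_i = sum_j beta_j(u_i) x_ij + eps_i.

#' Generate synthetic spatial units
#'
#' Produces `n` point units with unique coordinates in the unit square and
#' right-skewed integer population weights (log-normal, floored at 1),
#' emulating county centroids with unequal beneficiary counts.
#'
#' @param n Number of units (>= 20).
#' @param layout `"grid"` (near-square lattice), `"uniform-random"`, or
#'   `"clustered"` (Gaussian scatter around random centers).
#' @param seed Integer seed; output is a pure function of `(n, layout, seed)`.
#' @param pop_meanlog,pop_sdlog Log-normal parameters for populations.
#' @return Data frame with columns `unit_id`, `x`, `y`, `population`.
#' @examples
#' head(generate_units(25, "grid", seed = 1))
#' @export
generate_units <- function(n, layout = c("grid", "uniform-random", "clustered"),
                           seed = 1L, pop_meanlog = log(8000), pop_sdlog = 1) {
  layout <- match.arg(layout)
  if (!is.numeric(n) || n < 20) config_error("generate_units(): n must be >= 20")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  if (layout == "grid") {
    m <- ceiling(sqrt(n))
    g <- expand.grid(x = seq(0, 1, length.out = m), y = seq(0, 1, length.out = m))
    xy <- as.matrix(g[seq_len(n), c("x", "y")])
  } else if (layout == "uniform-random") {
    xy <- cbind(stats::runif(n), stats::runif(n))
  } else {
    n_centers <- max(3L, round(n / 80))
    centers <- cbind(stats::runif(n_centers, 0.15, 0.85),
                     stats::runif(n_centers, 0.15, 0.85))
    id <- sample.int(n_centers, n, replace = TRUE)
    xy <- centers[id, ] + matrix(stats::rnorm(2 * n, sd = 0.08), ncol = 2)
    xy <- pmin(pmax(xy, 0), 1)
  }
  pop <- pmax(1L, as.integer(round(stats::rlnorm(n, pop_meanlog, pop_sdlog))))
  units <- data.frame(unit_id = sprintf("u%04d", seq_len(n)),
                      x = xy[, 1], y = xy[, 2], population = pop,
                      stringsAsFactors = FALSE)
  validate_units(units)
}

#' Specify a true coefficient surface
#'
#' @param kind `"constant"`, `"gradient"`, or `"bump"`.
#' @param level Constant value (kind `"constant"`).
#' @param intercept,dx,dy Affine surface `intercept + dx*x + dy*y`
#'   (kind `"gradient"`).
#' @param center,radius,height,baseline Bisquare-profile bump: value is
#'   `baseline + height * (1 - (d/radius)^2)^2` within `radius` of `center`,
#'   `baseline` outside (kind `"bump"`).
#' @return A `surface_spec` object consumed by [make_surface()].
#' @export
surface_spec <- function(kind = c("constant", "gradient", "bump"),
                         level = 0, intercept = 0, dx = 0, dy = 0,
                         center = c(0.5, 0.5), radius = 0.3,
                         height = 1, baseline = 0) {
  kind <- match.arg(kind)
  params <- switch(kind,
    constant = list(level = level),
    gradient = list(intercept = intercept, dx = dx, dy = dy),
    bump = list(center = center, radius = radius, height = height,
                baseline = baseline))
  if (!all(vapply(params, function(p) all(is.finite(unlist(p))), logical(1)))) {
    config_error("surface_spec(): parameters must be finite")
  }
  if (kind == "bump" && radius <= 0) config_error("surface_spec(): bump radius must be > 0")
  structure(c(list(kind = kind), params), class = "surface_spec")
}

#' Evaluate a coefficient surface at unit locations
#'
#' @param spec A [surface_spec()].
#' @param units Unit data frame from [generate_units()].
#' @return Numeric vector of surface values, one per unit.
#' @export
make_surface <- function(spec, units) {
  if (!inherits(spec, "surface_spec")) config_error("make_surface(): not a surface_spec")
  x <- units$x; y <- units$y
  switch(spec$kind,
    constant = rep(spec$level, length(x)),
    gradient = spec$intercept + spec$dx * x + spec$dy * y,
    bump = {
      d <- sqrt((x - spec$center[1])^2 + (y - spec$center[2])^2)
      u <- d / spec$radius
      val <- rep(spec$baseline, length(x))
      inside <- u < 1
      val[inside] <- spec$baseline + spec$height * (1 - u[inside]^2)^2
      val
    },
    config_error("make_surface(): unknown surface kind '%s'", spec$kind))
}

#' Configure a synthetic dataset
#'
#' @param n_units Number of units (>= 20).
#' @param layout Spatial layout passed to [generate_units()].
#' @param surfaces Named list of [surface_spec()]s, one per model term; the
#'   first entry is the intercept surface, the rest the covariate surfaces.
#' @param rho Exchangeable pairwise correlation among covariates.
#' @param noise_sd Positive SD of the i.i.d. Gaussian noise.
#' @param pop_meanlog,pop_sdlog Population-weight distribution parameters.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_units, layout = "uniform-random", surfaces,
                             rho = 0, noise_sd = 0.3,
                             pop_meanlog = log(8000), pop_sdlog = 1, seed = 1L) {
  if (n_units < 20) config_error("synthetic_config(): n_units must be >= 20")
  if (noise_sd <= 0) config_error("synthetic_config(): noise_sd must be > 0")
  if (length(surfaces) < 2L) config_error("synthetic_config(): need intercept + >= 1 covariate surface")
  ok <- vapply(surfaces, inherits, logical(1), "surface_spec")
  if (!all(ok)) config_error("synthetic_config(): all surfaces must be surface_spec objects")
  if (is.null(names(surfaces))) {
    names(surfaces) <- c("(Intercept)", paste0("x", seq_len(length(surfaces) - 1L)))
  }
  k <- length(surfaces) - 1L
  if (k > 1L && (rho <= -1 / (k - 1) || rho >= 1)) {
    config_error("synthetic_config(): covariate correlation %.3f makes the correlation matrix non positive-definite", rho)
  }
  structure(list(n_units = as.integer(n_units), layout = layout,
                 surfaces = surfaces, rho = rho, noise_sd = noise_sd,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default validation preset
#'
#' A 400-unit, 6-covariate configuration mixing the three surface scales:
#' two constant (global) coefficients, two planar gradients (regional), and
#' two compact bumps (local), with moderate covariate correlation (0.3) and
#' noise SD 0.3. Surface amplitudes are of order 0.5 so each term contributes
#' comparably to the outcome variance.
#'
#' @param n Number of units.
#' @param seed Integer seed.
#' @param noise_sd Noise standard deviation.
#' @return A `synthetic_config`.
#' @export
synthetic_preset <- function(n = 400, seed = 11L, noise_sd = 0.3) {
  synthetic_config(
    n_units = n, layout = "uniform-random",
    surfaces = list(
      "(Intercept)" = surface_spec("constant", level = 0),
      const_pos = surface_spec("constant", level = 0.5),
      const_neg = surface_spec("constant", level = -0.4),
      grad_x = surface_spec("gradient", intercept = -0.5, dx = 1.0, dy = 0),
      grad_y = surface_spec("gradient", intercept = 0.6, dx = 0, dy = -1.2),
      bump_pos = surface_spec("bump", center = c(0.3, 0.3), radius = 0.35,
                              height = 1.5, baseline = 0),
      bump_neg = surface_spec("bump", center = c(0.7, 0.6), radius = 0.3,
                              height = -1.2, baseline = 0)
    ),
    rho = 0.3, noise_sd = noise_sd, seed = seed)
}

#' Simulate a dataset with known local coefficients
#'
#' Draws units, correlated standardized covariates and i.i.d. Gaussian noise,
#' evaluates each term's true coefficient surface at the unit locations, and
#' builds the outcome as the exact local linear predictor plus noise. Returns
#' both the fit-ready dataset and a truth bundle for recovery checks.
#'
#' @param config A [synthetic_config()] or [synthetic_preset()].
#' @return List with elements `data` (a [spatial_dataset()]) and `truth`
#'   (class `truth_bundle`: the n x (k+1) true coefficient matrix `beta` on
#'   the raw-outcome scale, the noise vector, and the config).
#' @details Covariates are z-scored at generation, so the linear predictor is
#'   already on a standardized-covariate scale; the dataset's outcome is then
#'   z-scored too. [standardized_truth()] rescales the true coefficients to
#'   the fully standardized scale the fitters report on.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) config_error("simulate_dataset(): not a synthetic_config")
  units <- generate_units(config$n_units, config$layout, seed = config$seed,
                          pop_meanlog = config$pop_meanlog, pop_sdlog = config$pop_sdlog)
  n <- nrow(units)
  k <- length(config$surfaces) - 1L

  set.seed(config$seed + 1000L)
  R <- matrix(config$rho, k, k); diag(R) <- 1
  L <- tryCatch(chol(R), error = function(e)
    config_error("simulate_dataset(): covariate correlation matrix is not positive-definite"))
  Z <- matrix(stats::rnorm(n * k), n, k) %*% L
  Z <- apply(Z, 2, standardize)
  colnames(Z) <- names(config$surfaces)[-1]

  B <- vapply(config$surfaces, make_surface, numeric(n), units = units)
  eps <- stats::rnorm(n, sd = config$noise_sd)
  y_raw <- B[, 1] + rowSums(B[, -1, drop = FALSE] * Z) + eps

  data <- spatial_dataset(units, y_raw, Z, metric = "euclidean")
  truth <- structure(list(beta = B, noise = eps, config = config,
                          y_center = data$scaling$y_center,
                          y_scale = data$scaling$y_scale),
                     class = "truth_bundle")
  list(data = data, truth = truth)
}

#' True coefficients on the standardized-outcome scale
#'
#' Rescales a truth bundle's coefficient surfaces to the scale on which
#' [fit_gwr()] / [fit_mgwr()] report: slopes divide by sd(y); the intercept
#' surface is additionally re-centered by mean(y).
#'
#' @param truth A `truth_bundle` from [simulate_dataset()].
#' @return n x (k+1) matrix of standardized-scale true coefficients.
#' @export
standardized_truth <- function(truth) {
  if (!inherits(truth, "truth_bundle")) config_error("standardized_truth(): not a truth_bundle")
  B <- truth$beta
  B[, 1] <- (B[, 1] - truth$y_center) / truth$y_scale
  B[, -1] <- B[, -1, drop = FALSE] / truth$y_scale
  B
}
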