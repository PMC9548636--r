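# Shared fixtures, memoized so expensive fits are computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# The default validation preset (n = 400, seed = 11): mixed constant /
# gradient / bump surfaces.
preset_sim <- function() memo("preset_sim", simulate_dataset(synthetic_preset()))
preset_D <- function() memo("preset_D", distance_matrix(preset_sim()$data))
preset_fit <- function() memo("preset_fit",
  fit_mgwr(preset_sim()$data, D = preset_D()))
preset_ols <- function() memo("preset_ols", fit_ols(preset_sim()$data))

# All-constant-surface dataset (n = 400): the stationary limit.
constant_config <- function(n = 400, seed = 11) {
  synthetic_config(n_units = n, surfaces = list(
    "(Intercept)" = surface_spec("constant", 0),
    c1 = surface_spec("constant", 0.5),
    c2 = surface_spec("constant", -0.3)),
    rho = 0.2, noise_sd = 0.3, seed = seed)
}
constant_sim <- function() memo("constant_sim", simulate_dataset(constant_config()))

# Small mixed dataset for the Monte Carlo studies (n = 150): one stationary
# and one strongly localized covariate.
mc_config <- function(seed) {
  synthetic_config(n_units = 150, surfaces = list(
    "(Intercept)" = surface_spec("constant", 0),
    c1 = surface_spec("constant", 0.5),
    b1 = surface_spec("bump", center = c(0.35, 0.35), radius = 0.35, height = 1.5)),
    rho = 0.3, noise_sd = 0.3, seed = seed)
}
mc_sim <- function() memo("mc_sim", simulate_dataset(mc_config(1)))
mc_fit <- function() memo("mc_fit",
  fit_mgwr(mc_sim()$data, mgwr_options(hat = FALSE)))

# One well-separated surface per scale class, for scale-recovery checks
# (n = 300; gradient slope 0.6 keeps the regional scale identifiable).
scale_config <- function(seed) {
  synthetic_config(n_units = 300, surfaces = list(
    "(Intercept)" = surface_spec("constant", 0),
    c1 = surface_spec("constant", 0.5),
    g1 = surface_spec("gradient", intercept = -0.3, dx = 0.6, dy = 0),
    b1 = surface_spec("bump", center = c(0.35, 0.35), radius = 0.3, height = 1.5)),
    rho = 0.3, noise_sd = 0.3, seed = seed)
}

# Columns with an exact sample correlation matrix R: orthonormalize centered
# Gaussian columns, then mix by chol(R). crossprod(X) == R exactly.
exact_corr_design <- function(n, R, seed = 1) {
  set.seed(seed)
  Z <- scale(matrix(rnorm(n * ncol(R)), n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  X <- Q %*% chol(R)
  colnames(X) <- paste0("x", seq_len(ncol(R)))
  X
}
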