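# Multiscale GWR: convergence criterion, corrected inference, back-fitting
# behavior and parameter recovery.

test_that("soc_f matches its closed form and invariances", {
  expect_equal(soc_f(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(soc_f(c(1, 1), c(2, 2)), 0.5)
  # permutation invariance under identical relabeling
  prev <- rnorm(20); curr <- rnorm(20)
  p <- sample(20)
  expect_equal(soc_f(prev[p], curr[p]), soc_f(prev, curr))
  # all-zero current fit falls back to the absolute form
  expect_equal(soc_f(c(1, 1), c(0, 0)), 1)
  expect_error(soc_f(1:3, 1:4), class = "mgwrdim_config_error")
})

test_that("corrected critical t spreads alpha over effective tests", {
  # ENP = 1: the ordinary two-sided critical value
  expect_equal(corrected_critical_t(0.05, 1, 500), qt(0.975, 500))
  # monotone in ENP
  cc <- vapply(c(1, 2, 5, 20), function(e) corrected_critical_t(0.05, e, 500),
               numeric(1))
  expect_true(all(diff(cc) > 0))
  # CDF-inversion oracle at alpha = 0.05, ENP = 2, df = 1000
  target <- 1 - (0.05 / 2) / 2
  oracle <- uniroot(function(q) pt(q, 1000) - target, c(0, 10), tol = 1e-10)$root
  expect_equal(corrected_critical_t(0.05, 2, 1000), oracle, tolerance = 1e-6)
  expect_warning(corrected_critical_t(0.05, 0.5, 100), "clipped")
  expect_error(corrected_critical_t(0.7, 2, 100), class = "mgwrdim_config_error")
})

test_that("stationary data drives every bandwidth to the global end", {
  sim <- constant_sim()
  fit <- fit_mgwr(sim$data)
  expect_true(all(fit$bandwidths >= 0.9 * 400))
  ols <- fit_ols(sim$data)
  expect_true(all(abs(colMeans(fit$coefficients) - ols$coefficients) < 0.05))
})

test_that("mixed scales separate: stationary terms smooth, bump terms local", {
  fit <- mc_fit()
  expect_gt(fit$bandwidths["c1"], 4 * fit$bandwidths["b1"])
  expect_lt(fit$bandwidths["b1"], 0.25 * 150)
})

test_that("with one covariate and stationary surfaces MGWR approaches the
           single-bandwidth GWR and the global fit", {
  cfg <- synthetic_config(n_units = 150, surfaces = list(
    "(Intercept)" = surface_spec("constant", 0),
    c1 = surface_spec("constant", 0.5)), noise_sd = 0.3, seed = 3)
  d <- simulate_dataset(cfg)$data
  m <- fit_mgwr(d, mgwr_options(hat = FALSE))
  g <- fit_gwr(d, kernel_spec(unname(m$bandwidths["c1"])))
  o <- fit_ols(d)
  # back-fitting of separate univariate smoothers is not algebraically the
  # joint local WLS fit, but on stationary data both sit near the global fit
  expect_lt(max(abs(m$coefficients - g$coefficients)), 0.1)
  expect_lt(mean(abs(sweep(m$coefficients, 2, o$coefficients))), 0.05)
})

test_that("per-term ENPs decompose the total hat trace", {
  fit <- preset_fit()
  expect_equal(sum(fit$enp), fit$trace_s, tolerance = 1e-6 * abs(fit$trace_s))
  expect_true(all(fit$enp > 0))
})

test_that("convergence trace decays and frozen sweeps do not inflate RSS", {
  fit <- preset_fit()
  expect_true(fit$converged)
  soc <- fit$soc_trace
  expect_true(all(diff(soc) <= 1e-10))
  if (length(fit$rss_trace) > 1) {
    expect_true(all(diff(fit$rss_trace) <= 1e-8))
  }
  # fitted decomposition: residuals + fitted = y
  d <- preset_sim()$data
  expect_equal(fit$fitted + fit$residuals, d$y, tolerance = 1e-12)
})

test_that("true coefficient surfaces are recovered on the default preset", {
  sim <- preset_sim()
  fit <- preset_fit()
  Bt <- standardized_truth(sim$truth)
  rmse <- sqrt(colMeans((fit$coefficients - Bt)^2))
  expect_true(all(rmse <= 0.15))
  expect_gt(cor(fit$coefficients[, "bump_pos"], Bt[, "bump_pos"]), 0.8)
  expect_gt(cor(fit$coefficients[, "bump_neg"], Bt[, "bump_neg"]), 0.8)
  expect_true(all(fit$bandwidths[c("const_pos", "const_neg")] >= 0.9 * 400))
})

test_that("MGWR beats the global model on heterogeneous data", {
  expect_lt(preset_fit()$aicc, preset_ols()$aicc)
})

test_that("surface scale classes are recovered across replicates", {
  cls <- t(vapply(1:10, function(s) {
    fit <- fit_mgwr(simulate_dataset(scale_config(100 + s))$data,
                    mgwr_options(hat = FALSE))
    scalability_class(fit$bandwidths, 300)
  }, character(4)))
  expect_gte(sum(cls[, "c1"] == "global"), 8)
  expect_gte(sum(cls[, "g1"] == "regional"), 8)
  expect_gte(sum(cls[, "b1"] == "local"), 8)
})

test_that("fit_mgwr validates inputs and carries non-convergence as status", {
  d <- mc_sim()$data
  expect_error(fit_mgwr(d, mgwr_options(search_range = c(2, 150))),
               class = "mgwrdim_config_error")
  small <- simulate_dataset(synthetic_config(n_units = 20, surfaces = list(
    "(Intercept)" = surface_spec("constant", 0),
    a = surface_spec("constant", 1), b = surface_spec("constant", 1),
    c = surface_spec("constant", 1), d = surface_spec("constant", 1),
    e = surface_spec("constant", 1), f = surface_spec("constant", 1)),
    noise_sd = 0.3, seed = 1))$data
  expect_error(fit_mgwr(small), class = "mgwrdim_config_error")
  expect_warning(
    capped <- fit_mgwr(d, mgwr_options(max_iter = 2, hat = FALSE)),
    "did not converge")
  expect_false(capped$converged)
})
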