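# Three-dimension disparity framework: level of influence, scalability,
# specificity, and the assembled report.

test_that("level of influence is population-weighted with a 50% cutoff", {
  sig <- cbind(a = c(FALSE, FALSE, TRUE), b = c(FALSE, FALSE, FALSE))
  pop <- c(10, 30, 60)
  res <- level_of_influence(sig, pop)
  expect_equal(res$influence_share, c(60, 0))
  expect_equal(res$influence_class, c("primary", "secondary"))
  # invariant under rescaling all populations
  res2 <- level_of_influence(sig, pop * 1000)
  expect_equal(res2$influence_share, res$influence_share)
  # share just above/below the cutoff
  expect_equal(level_of_influence(cbind(v = c(TRUE, FALSE)), c(51, 49))$influence_class, "primary")
  expect_equal(level_of_influence(cbind(v = c(TRUE, FALSE)), c(50, 50))$influence_class, "secondary")
  expect_error(level_of_influence(sig, c(0, 30, 60)), class = "mgwrdim_config_error")
})

test_that("scalability thresholds and classes follow the 75/25 rule", {
  th <- scalability_thresholds(3108)
  expect_equal(unname(th["hi"]), 2331)
  expect_equal(unname(th["lo"]), 777)
  # published-bandwidth cases
  expect_equal(scalability_class(44, 3108), "local")
  expect_equal(scalability_class(1474, 3108), "regional")
  expect_equal(scalability_class(3106, 3108), "global")
  # boundary behavior: the interval [lo, hi] is closed
  expect_equal(scalability_class(777, 3108), "regional")
  expect_equal(scalability_class(2331, 3108), "regional")
  expect_equal(scalability_class(776, 3108), "local")
  expect_equal(scalability_class(2332, 3108), "global")
  expect_error(scalability_class(0, 3108), class = "mgwrdim_config_error")
  expect_error(scalability_class(3109, 3108), class = "mgwrdim_config_error")
})

test_that("a reported label that contradicts the rule is flagged", {
  # bandwidth 2359 exceeds 0.75 * 3108 = 2331, so a 'regional' label conflicts
  expect_true(scalability_conflict(2359, 3108, "regional"))
  expect_false(scalability_conflict(1474, 3108, "regional"))
  expect_false(scalability_conflict(44, 3108, "local"))
  expect_error(scalability_conflict(44, 3108, "huge"), class = "mgwrdim_config_error")
})

test_that("specificity picks the largest |coefficient| and partitions units", {
  B <- rbind(c(0.2, -0.5), c(0.9, 0.1))
  colnames(B) <- c("v1", "v2")
  sp <- specificity(B)
  expect_equal(sp$dominant, c("v2", "v1"))
  expect_equal(unname(sp$counts), c(1, 1))

  # single covariate dominates everywhere
  one <- specificity(matrix(rnorm(10), ncol = 1, dimnames = list(NULL, "only")))
  expect_equal(unname(one$counts), 10)

  # ties break by column order, deterministically, and are reported
  Bt <- rbind(c(0.5, -0.5), c(0.3, 0.4))
  colnames(Bt) <- c("first", "second")
  expect_message(spt <- specificity(Bt), "tie")
  expect_equal(spt$dominant[1], "first")

  # partition invariant on random matrices
  set.seed(21)
  for (r in 1:5) {
    M <- matrix(rnorm(40 * 4), 40)
    expect_equal(sum(specificity(M)$counts), 40)
  }
  expect_error(specificity(rbind(c(1, NaN))), class = "mgwrdim_data_error")
})

test_that("dimension_report assembles all three dimensions coherently", {
  sim <- preset_sim()
  fit <- preset_fit()
  rep <- dimension_report(fit, sim$data)
  v <- rep$variables
  expect_equal(v$variable, fit$names)
  expect_true(all(v$scalability_class %in% c("global", "regional", "local")))
  # intercept excluded from influence and specificity
  expect_true(is.na(v$influence_share[1]))
  expect_true(is.na(v$dominance_count[1]))
  covs <- v[-1, ]
  expect_true(all(covs$influence_share >= 0 & covs$influence_share <= 100))
  expect_equal(sum(covs$dominance_count), 400)
  expect_equal(sum(covs$dominance_share), 100, tolerance = 0.1)
  expect_equal(nrow(rep$units), 400)
  expect_true(all(rep$units$dominant_variable %in% covs$variable))
  # nominal policy flags at least as many units as the corrected one
  rep_nom <- dimension_report(fit, sim$data, alpha_policy = "nominal")
  expect_true(all(rep_nom$variables$influence_share[-1] >= covs$influence_share))
})

test_that("a null covariate is secondary, global-scale and never dominant", {
  cfg <- synthetic_config(n_units = 200, surfaces = list(
    "(Intercept)" = surface_spec("constant", 0),
    strong = surface_spec("constant", 0.8),
    null_x = surface_spec("constant", 0)),
    rho = 0, noise_sd = 0.3, seed = 31)
  sim <- simulate_dataset(cfg)
  fit <- fit_mgwr(sim$data)
  rep <- dimension_report(fit, sim$data)
  row <- rep$variables[rep$variables$variable == "null_x", ]
  expect_equal(row$influence_class, "secondary")
  expect_equal(row$scalability_class, "global")
  expect_equal(row$dominance_count, 0)
})
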