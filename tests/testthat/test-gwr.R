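# GWR engine: distances, kernel, local fits, hat matrix, bandwidth search.

test_that("distance_matrix satisfies metric basics", {
  u <- data.frame(unit_id = c("a", "b", "c"), x = c(0, 3, 1),
                  y = c(0, 4, 1), population = c(1, 1, 1))
  D <- distance_matrix(u, "euclidean")
  expect_equal(diag(D), rep(0, 3))
  expect_equal(D, t(D))
  expect_equal(D[1, 2], 5)
  # triangle inequality
  expect_lte(D[1, 2], D[1, 3] + D[3, 2] + 1e-12)

  # haversine: identical lon/lat -> 0; known meridian arc ~111.2 km/degree
  ug <- data.frame(unit_id = c("p", "q", "r"), x = c(10, 10, 10),
                   y = c(50, 50 + 1e-9, 51), population = c(1, 1, 1))
  Dg <- distance_matrix(ug, "haversine")
  expect_equal(Dg[1, 2], 0, tolerance = 1e-6)
  expect_equal(Dg[1, 3], 111.2, tolerance = 0.5)
})

test_that("adaptive bisquare weights match the kernel's closed form", {
  dist_row <- c(0, 1, 2, 3, 4, 6)
  w <- adaptive_bisquare(dist_row, k_neighbors = 5)  # b = 4th distance after self... b = 4
  b <- 4
  expect_equal(w[1], 1)                     # self, d = 0
  expect_equal(w[5], 0)                     # d == b: open support
  expect_equal(w[3], (1 - (2 / b)^2)^2)     # interior point
  expect_equal(adaptive_bisquare(c(0, 2, 4), 3)[2], (1 - 0.25)^2)  # d = b/2 -> 0.5625
  expect_equal(sum(w > 0), 4)               # k nearest minus the boundary tie
  expect_error(adaptive_bisquare(dist_row, 1), class = "mgwrdim_config_error")
  expect_error(adaptive_bisquare(dist_row, 10), class = "mgwrdim_config_error")
})

test_that("local_fit solves the weighted normal equations (brute-force oracle)", {
  set.seed(42)
  n <- 12
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- rnorm(n)
  w <- runif(n, 0.1, 1)
  # oracle: assemble X'WX and X'Wy element by element
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (i in seq_len(n)) {
    for (r in 1:3) {
      b[r] <- b[r] + w[i] * X[i, r] * y[i]
      for (s in 1:3) A[r, s] <- A[r, s] + w[i] * X[i, r] * X[i, s]
    }
  }
  beta_oracle <- solve(A, b)
  expect_equal(local_fit(X, y, w)$coefficients, beta_oracle, tolerance = 1e-10)

  # intercept-only design: the weighted mean
  expect_equal(local_fit(matrix(1, n, 1), y, w)$coefficients,
               weighted.mean(y, w), tolerance = 1e-12)

  # all-ones weights: global OLS
  expect_equal(local_fit(X, y, rep(1, n))$coefficients,
               unname(coef(lm(y ~ X[, 2] + X[, 3]))), tolerance = 1e-8)

  # too few positive weights for the parameter count
  expect_error(local_fit(X, y, c(1, 1, rep(0, n - 2))),
               class = "mgwrdim_singularity_error")
})

test_that("fit_gwr is internally consistent (fitted, hat, trace)", {
  d <- mc_sim()$data
  g <- fit_gwr(d, kernel_spec(40))
  # fitted values are X beta row-wise
  expect_equal(g$fitted, rowSums(d$X * g$coefficients), tolerance = 1e-10)
  # hat matrix reproduces the fit
  expect_equal(as.vector(g$hat %*% d$y), g$fitted, tolerance = 1e-8)
  # trace two ways: stored diagonal vs independent per-unit recomputation
  D <- distance_matrix(d)
  tr2 <- sum(vapply(seq_len(nrow(d$X)), function(i) {
    w <- adaptive_bisquare(D[i, ], 40)
    Xw <- d$X * w
    as.numeric(d$X[i, ] %*% solve(crossprod(Xw, d$X), d$X[i, ]))
  }, numeric(1)))
  expect_equal(g$trace_s, tr2, tolerance = 1e-8)
  expect_true(all(g$local_r2 <= 1))
  expect_gt(g$trace_s, 0)
  expect_lte(g$trace_s, nrow(d$X))
})

test_that("near-global bandwidth on stationary data gives flat surfaces", {
  sim <- constant_sim()
  g <- fit_gwr(sim$data, kernel_spec(400))
  expect_true(all(apply(g$coefficients, 2, sd) < 0.02))
})

test_that("moderate bandwidth recovers a bump surface", {
  sim <- preset_sim()
  g <- fit_gwr(sim$data, kernel_spec(50), D = preset_D())
  Bt <- standardized_truth(sim$truth)
  expect_gt(cor(g$coefficients[, "bump_pos"], Bt[, "bump_pos"]), 0.8)
  expect_gt(cor(g$coefficients[, "bump_neg"], Bt[, "bump_neg"]), 0.8)
})

test_that("local-coefficient variance is non-increasing in bandwidth", {
  sim <- preset_sim()
  grid <- c(60, 120, 200, 300, 400)
  v <- vapply(grid, function(k) {
    mean(apply(fit_gwr(sim$data, kernel_spec(k), D = preset_D())$coefficients, 2, var))
  }, numeric(1))
  expect_true(all(diff(v) <= 1e-10))
})

test_that("bandwidth selection prefers the right scale", {
  # stationary data -> near-global bandwidth
  expect_gte(select_bandwidth(constant_sim()$data), 0.9 * 400)
  # bump-dominated data -> clearly sub-global bandwidth
  expect_lt(select_bandwidth(preset_sim()$data, D = preset_D()), 0.5 * 400)
})

test_that("bandwidth search validates its range", {
  d <- mc_sim()$data
  expect_error(select_bandwidth(d, range = c(2, 150)), class = "mgwrdim_config_error")
  expect_error(select_bandwidth(d, range = c(10, 9999)), class = "mgwrdim_config_error")
  expect_error(fit_gwr(d, kernel_spec(3)), class = "mgwrdim_config_error")
  expect_error(fit_gwr(d, kernel_spec(151)), class = "mgwrdim_config_error")
})
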