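test_that("histogram density estimator is exact on constructed samples", {
  g <- phase_grid(4, gamma_point(0))
  d <- estimate_density(c(-pi, -pi / 2, 0, pi / 2), rep(0, 4), g)
  expect_equal(as.numeric(d), rep(1 / (2 * pi), 4))
  # all mass in one bin
  d2 <- estimate_density(rep(0.1, 7), rep(0, 7), g)
  expect_equal(d2[3, 1], 1 / g$dtheta)
  expect_equal(sum(d2 != 0), 1L)
  expect_equal(grid_integral(d2, g), 1)
  # phases outside the domain are wrapped first
  expect_equal(estimate_density(2 * pi + 0.1, 0, g),
               estimate_density(0.1, 0, g))
})

test_that("histogram of many uniform draws is flat to binomial error", {
  g <- phase_grid(64, gamma_point(0))
  set.seed(9)
  n <- 2e5
  d <- estimate_density(runif(n, -pi, pi), rep(0, n), g)
  p <- g$dtheta / (2 * pi)
  se_bin <- sqrt(p * (1 - p) / n) / g$dtheta   # SE of one bin's density
  expect_lt(max(abs(d - 1 / (2 * pi))), 5 * se_bin)
  expect_equal(grid_integral(d, g), 1, tolerance = 1e-12)
})

test_that("ensemble mean drive matches the uncoupled closed form", {
  m <- model_spec(N = 100, beta = 1, drive = 1, gamma_law = gamma_point(0))
  tt <- seq(0.5, 4, by = 0.5)
  st <- run_ensemble(m, R = 2000, base_seed = 21, grid = grid_for(m),
                     sample_times = tt, estimate = "u")
  exact <- uncoupled_mean_u(tt, beta = 1, I = 1)
  expect_true(all(abs(st$mean_u - exact) < 3 * st$se_mean_u + 1e-12))
  # C11_hat should be near the independent-oracle variance
  o <- uncoupled_oracle(4, beta = 1, I = 1)
  expect_lt(abs(st$C11_hat[length(tt)] - o$C11), 4 * st$se_C11[length(tt)])
})

test_that("ensemble estimators obey their structural properties", {
  m <- coupled_model(N = 100)
  tt <- c(1, 3)
  st <- run_ensemble(m, R = 400, base_seed = 31, grid = grid_for(m),
                     sample_times = tt, return_raw = TRUE)
  # density integrates to one at every sample time
  for (s in seq_along(tt)) {
    expect_equal(sum(st$density[, , s]) * st$grid$dtheta, 1,
                 tolerance = 1e-12)
  }
  # C11_hat nonnegative up to noise
  expect_true(all(st$C11_hat > -3 * st$se_C11))
  # permutation invariance of the estimators
  u <- st$u_mat
  perm <- sample(nrow(u))
  expect_equal(colMeans(u[perm, ]), st$mean_u)
  # split-half consistency of the mean
  h1 <- colMeans(u[1:200, ]); h2 <- colMeans(u[201:400, ])
  se <- apply(u, 2, sd) / sqrt(200)
  expect_true(all(abs(h1 - h2) < 4 * sqrt(2) * se))
  expect_error(run_ensemble(m, R = 1, base_seed = 1, grid = grid_for(m),
                            sample_times = 1), "R >= 2")
})

test_that("standard errors shrink like 1/sqrt(R)", {
  m <- coupled_model(N = 50)
  s1 <- run_ensemble(m, R = 100, base_seed = 41, grid = grid_for(m),
                     sample_times = c(2), estimate = "u")
  s2 <- run_ensemble(m, R = 400, base_seed = 41, grid = grid_for(m),
                     sample_times = c(2), estimate = "u")
  expect_equal(s1$se_mean_u / s2$se_mean_u, 2, tolerance = 0.35)
})

test_that("scaling check compares ensembles against a mean-field reference", {
  m1 <- coupled_model(N = 100)
  m2 <- coupled_model(N = 200)
  tt <- seq(0, 4, by = 0.5)
  s1 <- run_ensemble(m1, R = 150, base_seed = 51, grid = grid_for(m1),
                     sample_times = tt, estimate = "u")
  s2 <- run_ensemble(m2, R = 150, base_seed = 51, grid = grid_for(m2),
                     sample_times = tt, estimate = "u")
  mf <- solve_mean_field(m1, grid_for(m1), T = 4, dt = 1e-3)
  rep <- scaling_check(s1, s2, mf)
  expect_named(rep, c("e_N", "e_2N", "ratio", "resolved", "err_N", "err_2N",
                      "se_N", "se_2N"))
  expect_gt(rep$e_N, 0)
  # identical stats give ratio exactly 1
  same <- scaling_check(s1, s1, mf)
  expect_equal(same$ratio, 1)
  expect_error(scaling_check(s1, s2, mf$a1_series[1:3]), "length")
})
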