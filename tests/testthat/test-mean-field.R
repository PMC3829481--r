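test_that("uncoupled mean field reproduces the scalar closed form", {
  m <- uncoupled_model(beta = 2, I = 1)
  sol <- solve_mean_field(m, grid_for(m), T = 3, dt = 1e-3)
  exact <- (1 - exp(-2 * sol$times)) / (2 * pi)
  expect_lt(max(abs(sol$a1_series - exact)), 1e-10)
})

test_that("Wilson-Cowan reduction matches its closed form and fixed point", {
  m <- uncoupled_model(beta = 2, I = 1)
  a1 <- wilson_cowan_reduced(m, T = 1, dt = 1e-3)
  expect_equal(a1[length(a1)], (1 - exp(-2)) / (2 * pi), tolerance = 1e-10)
  m0 <- model_spec(N = 10, beta = 1, drive = 0, gamma_law = gamma_point(0.4))
  expect_equal(max(abs(wilson_cowan_reduced(m0, T = 5, dt = 1e-2))), 0)
  # gbar = 1, I = 1: fixed point I / (2 pi - gbar)
  m1 <- model_spec(N = 10, beta = 1, drive = 1, gamma_law = gamma_point(1))
  a2 <- wilson_cowan_reduced(m1, T = 25, dt = 1e-3)
  expect_equal(a2[length(a2)], 1 / (2 * pi - 1), tolerance = 1e-7)
})

test_that("the reduction refuses invalid regimes", {
  mb <- model_spec(N = 10, beta = 1, drive = 1, rho0 = rho_bump(0, 1))
  expect_error(wilson_cowan_reduced(mb, T = 1, dt = 1e-2), "uniform")
  mt <- model_spec(N = 10, beta = 1, drive = 1, dynamics_kind = "theta")
  expect_error(solve_mean_field(mt, phase_grid(32, mt$gamma_law), 1, 1e-2,
                                method = "characteristics"), "grid_advection")
})

test_that("density advection is an exact rigid rotation for linear phase", {
  m <- model_spec(N = 10, beta = 1, drive = 1, gamma_law = gamma_point(0),
                  rho0 = rho_bump(0, 2))
  g <- grid_for(m)
  sol <- solve_mean_field(m, g, T = 2, dt = 1e-3, snapshot_times = 2)
  expected <- rho0_density(rho_bump(0, 2), g$theta_nodes - 2)  # shift I * t
  expect_lt(max(abs(sol$a3_fields[[1]] - expected)), 1e-10)
  expect_equal(grid_integral(sol$a3_fields[[1]], g), 1, tolerance = 1e-10)
})

test_that("characteristics and grid advection agree within scheme accuracy", {
  m <- coupled_model(N = 200)
  g <- grid_for(m)
  mc <- solve_mean_field(m, g, T = 5, dt = 5e-3)
  mg <- solve_mean_field(m, g, T = 5, dt = 5e-3, method = "grid_advection")
  # splitting scheme is low order in time; characteristics is near exact
  expect_lt(max(abs(mc$a1_series - mg$a1_series)), 1e-3)
  # both settle on the same asynchronous fixed point
  expect_lt(abs(mg$a1_series[length(mg$times)] -
                  mc$a1_series[length(mc$times)]), 2e-4)
})

test_that("gamma mixtures average into the Wilson-Cowan gain", {
  gl <- gamma_mixture(c(0.25, 0.75), c(0.5, 0.5))
  m <- model_spec(N = 10, beta = 1, drive = 1, gamma_law = gl)
  sol <- solve_mean_field(m, phase_grid(64, gl), T = 25, dt = 1e-3)
  expect_equal(sol$a1_series[length(sol$times)], 1 / (2 * pi - 0.5),
               tolerance = 1e-6)  # fixed point with gbar = 0.5
})

test_that("theta-model upwind solver conserves mass and tracks ensembles", {
  gl <- gamma_point(0.3)
  m <- model_spec(N = 400, beta = 1, drive = 1, gamma_law = gl,
                  dynamics_kind = "theta")
  g <- phase_grid(128, gl)
  sol <- solve_mean_field(m, g, T = 4, dt = 5e-4, method = "grid_advection",
                          snapshot_times = c(2, 4))
  for (f in sol$a3_fields) {
    expect_equal(grid_integral(f, g), 1, tolerance = 1e-10)
  }
  st <- run_ensemble(m, R = 150, base_seed = 61, grid = g,
                     sample_times = c(2, 4), mode = "fixed_step", dt = 2e-3,
                     estimate = "u")
  k <- vapply(c(2, 4), function(s) which.min(abs(sol$times - s)), 1L)
  expect_true(all(abs(sol$a1_series[k] - st$mean_u) <
                    4 * st$se_mean_u + 0.01))  # first-order scheme slack
})
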