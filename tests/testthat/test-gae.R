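test_that("moment initialization encodes the i.i.d. draw covariances", {
  m <- coupled_model(N = 200)
  g <- phase_grid(64, m$gamma_law)
  st <- init_moments(m, g, "ordinary")
  expect_equal(st$a1, m$u0)
  expect_equal(st$C11, 0)
  expect_equal(max(abs(st$C)), 0)
  # ordinary: off-diagonal -rho0 rho0' = -1/(4 pi^2) for uniform rho0
  off <- st$C33[row(st$C33) != col(st$C33)]
  expect_equal(unique(round(off, 12)), round(-1 / (4 * pi^2), 12))
  # rows integrate to zero: total density is fixed at 1 per realization
  measure <- rep(g$dtheta * g$gamma_weights, each = g$M)
  expect_lt(max(abs(st$C33 %*% measure)), 1e-10)
  # factorial subtracts the diagonal self-term: constant everywhere
  stf <- init_moments(m, g, "factorial")
  expect_equal(max(abs(stf$C33 + 1 / (4 * pi^2))), 0, tolerance = 1e-12)
  expect_equal(st$C33 - diag(as.numeric(st$a3) / (g$dtheta), g$M),
               stf$C33, tolerance = 1e-12)
})

test_that("dropping the 1/N terms reproduces the mean-field solver exactly", {
  m <- coupled_model(N = 200)
  g <- phase_grid(32, m$gamma_law)
  gae0 <- solve_gae(m, g, T = 3, dt = 0.01, fluctuation_terms = FALSE)
  mfg <- solve_mean_field(m, g, T = 3, dt = 0.01, method = "grid_advection")
  expect_lt(max(abs(gae0$a1_series - mfg$a1_series)), 1e-12)
  # and the characteristics solver agrees to scheme accuracy
  mfc <- solve_mean_field(m, g, T = 3, dt = 0.01)
  expect_lt(max(abs(gae0$a1_series - mfc$a1_series)), 1e-3)
})

test_that("with gamma = 0 the density stays exactly uniform", {
  m <- uncoupled_model(N = 200, beta = 1, I = 1)
  g <- phase_grid(32, m$gamma_law)
  sol <- solve_gae(m, g, T = 2, dt = 0.01, snapshot_times = 2)
  a3 <- sol$snapshots[[1]]$a3
  expect_lt(max(abs(a3 - 1 / (2 * pi))), 1e-12)
})

test_that("uncoupled covariances match the independent per-neuron oracle", {
  m <- uncoupled_model(N = 200, beta = 1, I = 1)
  g <- phase_grid(64, m$gamma_law)
  sol <- solve_gae(m, g, T = 5, dt = 0.005)
  for (tt in c(1, 3, 5)) {
    o <- uncoupled_oracle(tt, beta = 1, I = 1)
    k <- which.min(abs(sol$times - tt))
    expect_equal(sol$C11_series[k], o$C11, tolerance = 0.05)
    expect_equal(sol$a1_series[k], o$mean_u, tolerance = 1e-3)
  }
  expect_length(sol$run_log, 0)
})

test_that("the ordinary cumulant convention reproduces raw Monte-Carlo
           statistics where the factorial one does not", {
  m <- uncoupled_model(N = 200, beta = 1, I = 1)
  g <- phase_grid(64, m$gamma_law)
  o <- uncoupled_oracle(4, beta = 1, I = 1)
  ord <- solve_gae(m, g, T = 4, dt = 0.005, convention = "ordinary")
  fac <- solve_gae(m, g, T = 4, dt = 0.005, convention = "factorial")
  k <- length(ord$times)
  expect_lt(abs(ord$C11_series[k] - o$C11) / o$C11, 0.05)
  # the factorial reading keeps the full 2 beta firing-line source and
  # overshoots the raw drive variance by roughly a factor two
  expect_gt(abs(fac$C11_series[k] - o$C11) / o$C11, 1)
})

test_that("C33 stays swap symmetric and C11 nonnegative through stepping", {
  m <- coupled_model(N = 200)
  g <- phase_grid(32, m$gamma_law)
  st <- init_moments(m, g)
  for (k in 1:50) {
    st <- step_gae(st, m, dt = 0.02)
    expect_lt(max(abs(st$C33 - t(st$C33))), 1e-10)
    expect_gt(st$C11, -1e-8)
  }
  expect_equal(st$t, 1, tolerance = 1e-12)
  # stepping one-at-a-time agrees with the batch solver
  sol <- solve_gae(m, g, T = 1, dt = 0.02)
  k <- length(sol$times)
  expect_equal(st$a1, sol$a1_series[k], tolerance = 1e-9)
  expect_equal(st$C11, sol$C11_series[k], tolerance = 1e-6)
})

test_that("an effectively infinite network collapses onto mean field", {
  gl <- gamma_point(0.5)
  m <- model_spec(N = 1e9, beta = 1, drive = 1, gamma_law = gl)
  g <- phase_grid(32, gl)
  full <- solve_gae(m, g, T = 3, dt = 0.01)
  bare <- solve_gae(m, g, T = 3, dt = 0.01, fluctuation_terms = FALSE)
  expect_lt(max(abs(full$a1_series - bare$a1_series)), 1e-8)
})

test_that("time-step refinement self-converges at first order or better", {
  m <- coupled_model(N = 200)
  g <- phase_grid(32, m$gamma_law)
  aT <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    sol <- solve_gae(m, g, T = 2, dt = dt)
    sol$a1_series[length(sol$times)]
  }, numeric(1))
  e1 <- abs(aT[1] - aT[2])
  e2 <- abs(aT[2] - aT[3])
  expect_lt(e2, 0.75 * e1)   # observed order >= 1
})

test_that("gamma mixtures propagate per-component covariances", {
  gl <- gamma_mixture(c(0.25, 0.75), c(0.5, 0.5))
  m <- model_spec(N = 200, beta = 1, drive = 1, gamma_law = gl)
  g <- phase_grid(32, gl)
  sol <- solve_gae(m, g, T = 3, dt = 0.01, snapshot_times = 3)
  st <- sol$snapshots[[1]]
  expect_equal(dim(st$C), c(32L, 2L))
  expect_equal(dim(st$C33), c(64L, 64L))
  expect_lt(max(abs(st$C33 - t(st$C33))), 1e-10)
  expect_equal(grid_integral(st$a3, g), 1, tolerance = 1e-10)
  expect_gt(st$C11, 0)
})
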