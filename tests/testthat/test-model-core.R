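test_that("phase-velocity law matches both dynamics families", {
  # linear_phase: F = I + gamma u, independent of theta
  expect_equal(velocity(0.3, gamma = 0, u = 7, I = 1.5, "linear_phase"), 1.5)
  expect_equal(velocity(-2, gamma = 2, u = 0.25, I = 1, "linear_phase"), 1.5)
  # theta model: 1 - cos + (1 + cos)(I + gamma u)
  expect_equal(velocity(pi, gamma = 5, u = 11, I = -3, "theta"), 2)
  expect_equal(velocity(0, gamma = 1, u = 0, I = 0.5, "theta"), 1)
  expect_error(velocity(0, 0, 0, 1, "voltage"), "arg")
})

test_that("linear_phase velocity is translation invariant, theta periodic", {
  set.seed(1)
  th <- runif(50, -10, 10)
  shift <- runif(50, -10, 10)
  expect_equal(velocity(th + shift, 0.7, 2, 1, "linear_phase"),
               velocity(th, 0.7, 2, 1, "linear_phase"))
  expect_equal(velocity(th + 2 * pi, 0.7, 2, 1, "theta"),
               velocity(th, 0.7, 2, 1, "theta"))
  # spiking speed at the firing phase is drive independent
  expect_equal(velocity(rep(pi, 5), runif(5), runif(5), runif(5), "theta"),
               rep(2, 5))
})

test_that("firing rate is the gamma-weighted flux through the firing phase", {
  expect_equal(firing_rate(1 / (2 * pi), u = 99, I = 1, gamma_point(0)),
               1 / (2 * pi))
  expect_equal(firing_rate(c(0, 0), u = 1, I = 1,
                           gamma_mixture(c(0, 1), c(0.5, 0.5))), 0)
  expect_equal(firing_rate(1 / (2 * pi), u = 0.5, I = 1, gamma_point(1)),
               1.5 / (2 * pi))
  expect_error(firing_rate(c(0.1, 0.2), u = 0, I = 1, gamma_point(0)),
               "length")
})

test_that("firing rate is linear in density and quadrature weights", {
  gl <- gamma_mixture(c(0.2, 0.8), c(0.3, 0.7))
  set.seed(2)
  for (k in 1:5) {
    d1 <- runif(2); d2 <- runif(2); a <- runif(1, -2, 2)
    expect_equal(firing_rate(d1 + a * d2, 0.4, 1.2, gl),
                 firing_rate(d1, 0.4, 1.2, gl) +
                   a * firing_rate(d2, 0.4, 1.2, gl))
  }
})

test_that("gamma laws validate nodes and weights", {
  gl <- gamma_mixture(c(0, 1), c(0.25, 0.75))
  expect_equal(sum(gl$weights), 1)
  expect_error(gamma_mixture(c(0, 1), c(0.5, 0.6)), "sum to 1")
  expect_error(gamma_mixture(c(0, 1), c(-0.5, 1.5)), "nonnegative")
  expect_equal(gamma_point(0.5)$nodes, 0.5)
})

test_that("initial densities normalize and evaluate correctly", {
  expect_equal(rho0_density(rho_uniform(), c(-1, 0, 2)), rep(1 / (2 * pi), 3))
  # wrapped bump integrates to 1 (trapezoid over a fine grid)
  th <- seq(-pi, pi, length.out = 20001)
  v <- rho0_density(rho_bump(0.5, 3), th)
  expect_equal(sum(diff(th) * (v[-1] + v[-length(v)]) / 2), 1,
               tolerance = 1e-8)
  # tabulated: validation and periodic interpolation
  dth <- 2 * pi / 128
  tab_th <- seq(-pi, pi - dth, length.out = 128)
  tab_v <- rho0_density(rho_bump(0, 2), tab_th)
  law <- rho_tabulated(tab_th, tab_v / (sum(tab_v) * dth))
  expect_s3_class(law, "rho0_law")
  expect_error(rho_tabulated(tab_th, tab_v * 2), "integrate to 1")
  expect_error(rho_tabulated(tab_th, -tab_v), "nonnegative")
  # interpolant reproduces the table at its own nodes
  expect_equal(rho0_density(law, tab_th), law$values, tolerance = 1e-12)
})

test_that("drive specifications interpolate and integrate", {
  d <- drive_tabulated(c(0, 1, 2), c(1, 3, 3))
  expect_equal(drive_value(d, 0.5), 2)        # linear interpolation
  expect_equal(drive_value(d, 10), 3)         # constant extension
  f <- spikemoments:::drive_integral_fun(d)
  expect_equal(f(2), 2 + 3)                   # trapezoid: 2 then 3
  expect_equal(f(4), 5 + 6)                   # constant tail
  fc <- spikemoments:::drive_integral_fun(drive_constant(2))
  expect_equal(fc(3.5), 7)
})

test_that("model_spec validates its fields", {
  expect_error(model_spec(N = 0, beta = 1, drive = 1), "positive integer")
  expect_error(model_spec(N = 10, beta = -1, drive = 1), "positive rate")
  m <- model_spec(N = 10, beta = 1, drive = 2)
  expect_equal(m$drive$kind, "constant")
  expect_output(print(m), "N = 10")
})

test_that("phase grid geometry and integration are exact", {
  g <- phase_grid(8, gamma_point(0))
  expect_equal(g$dtheta * g$M, 2 * pi)
  expect_equal(g$theta_nodes[g$firing_node], -pi)  # identified with +pi
  expect_equal(grid_integral(matrix(1 / (2 * pi), 8, 1), g), 1)
  gl <- gamma_mixture(c(0, 1), c(0.4, 0.6))
  g2 <- phase_grid(16, gl)
  expect_equal(grid_integral(rho0_on_grid(rho_bump(1, 2), g2), g2), 1)
})

test_that("angle wrapping lands in [-pi, pi)", {
  expect_equal(wrap_angle(pi), -pi)
  expect_equal(wrap_angle(-pi), -pi)
  expect_equal(wrap_angle(3 * pi + 0.5), -pi + 0.5)
  x <- seq(-20, 20, length.out = 101)
  expect_true(all(wrap_angle(x) >= -pi & wrap_angle(x) < pi))
})
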