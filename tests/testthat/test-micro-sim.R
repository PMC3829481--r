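test_that("initial state sampling follows the declared laws", {
  m <- model_spec(N = 1e5, beta = 1, drive = 1, gamma_law = gamma_point(0.5))
  init <- draw_initial_state(m, seed = 3)
  # KS distance of phases from uniform on [-pi, pi)
  ks <- max(abs(sort((init$phases + pi) / (2 * pi)) -
                  (seq_len(m$N) - 0.5) / m$N))
  expect_lt(ks, 0.01)
  expect_true(all(init$gammas == 0.5))
  expect_identical(init, draw_initial_state(m, seed = 3))  # determinism
  # mixture sampling hits the node frequencies
  mm <- model_spec(N = 1e4, beta = 1, drive = 1,
                   gamma_law = gamma_mixture(c(0, 1), c(0.25, 0.75)))
  g2 <- draw_initial_state(mm, seed = 4)$gammas
  expect_true(all(g2 %in% c(0, 1)))
  expect_equal(mean(g2 == 1), 0.75, tolerance = 0.05)
  # bump sampling concentrates at the center
  mb <- model_spec(N = 2e4, beta = 1, drive = 1, rho0 = rho_bump(1, 4))
  ph <- draw_initial_state(mb, seed = 5)$phases
  expect_equal(mean(cos(ph - 1)), besselI(4, 1) / besselI(4, 0),
               tolerance = 0.02)  # von Mises resultant length
})

test_that("single neuron and degenerate cases fire as the dynamics dictate", {
  m <- model_spec(N = 1, beta = 1, drive = 1, gamma_law = gamma_point(0))
  tr <- simulate_network(m, seed = 1, T = 10,
                         init = list(phases = 0, gammas = 0, u0 = 0))
  expect_equal(tr$spikes$time[1], pi, tolerance = 1e-10)
  expect_equal(diff(tr$spikes$time), rep(2 * pi, nrow(tr$spikes) - 1),
               tolerance = 1e-9)  # ISI = 2 pi / I for gamma = 0
  # zero velocity: no crossings ever
  m0 <- model_spec(N = 3, beta = 1, drive = 0, gamma_law = gamma_point(0))
  tr0 <- simulate_network(m0, seed = 2, T = 50)
  expect_equal(nrow(tr0$spikes), 0L)
  expect_error(simulate_network(m, seed = 1, T = -1), "positive")
})

test_that("event-driven and dense fixed-step runs agree spike for spike", {
  m <- model_spec(N = 10, beta = 1, drive = 1, gamma_law = gamma_point(0.8))
  te <- simulate_network(m, seed = 7, T = 15, mode = "event_driven")
  tf <- simulate_network(m, seed = 7, T = 15, mode = "fixed_step", dt = 1e-4)
  expect_equal(nrow(te$spikes), nrow(tf$spikes))
  expect_lt(max(abs(te$spikes$time - tf$spikes$time)), 1e-8)
  expect_identical(te$spikes$neuron, tf$spikes$neuron)
  expect_lt(max(abs(te$u_series - tf$u_series)), 1e-8)
})

test_that("closed-form drive propagation matches its definition", {
  out <- drive_between_events(1, beta = 2, delta_t = 1)
  expect_equal(out$u, exp(-2))
  expect_equal(out$integral_u, (1 - exp(-2)) / 2)
  expect_equal(drive_between_events(0, 5, 3), list(u = 0, integral_u = 0))
  # small-interval limit: integral -> u_k * dt
  expect_equal(drive_between_events(1, 1, 1e-8)$integral_u / 1e-8, 1,
               tolerance = 1e-6)
})

test_that("the event ledger is conserved: jumps + decay reproduce u", {
  m <- model_spec(N = 20, beta = 1.5, drive = 1,
                  gamma_law = gamma_point(0.6))
  tr <- simulate_network(m, seed = 11, T = 12)
  expect_equal(nrow(tr$spikes), as.integer(tr$n_events))
  u <- draw_initial_state(m, 11)$u0
  tprev <- 0
  for (ts in tr$spikes$time) {
    u <- drive_between_events(u, m$beta, ts - tprev)$u + m$beta / m$N
    tprev <- ts
  }
  u <- drive_between_events(u, m$beta, max(tr$sample_times) - tprev)$u
  expect_equal(u, tr$u_final, tolerance = 1e-12)
})

test_that("seeded runs are reproducible and seeds matter", {
  m <- coupled_model(N = 50)
  a <- simulate_network(m, seed = 5, T = 8)
  b <- simulate_network(m, seed = 5, T = 8)
  c <- simulate_network(m, seed = 6, T = 8)
  expect_identical(a$u_series, b$u_series)
  expect_identical(a$spikes, b$spikes)
  expect_false(identical(a$u_series, c$u_series))
})

test_that("theta-model dynamics integrate correctly in fixed-step mode", {
  # I = 1 makes the theta-neuron speed exactly 2: first spike at pi/2 from 0
  mt <- model_spec(N = 1, beta = 1, drive = 1, gamma_law = gamma_point(0),
                   dynamics_kind = "theta")
  tr <- simulate_network(mt, seed = 1, T = 10, mode = "fixed_step", dt = 1e-4,
                         init = list(phases = 0, gammas = 0, u0 = 0))
  expect_equal(tr$spikes$time[1], pi / 2, tolerance = 1e-6)
  expect_equal(diff(tr$spikes$time)[1], pi, tolerance = 1e-6)
  # sub-threshold external drive: never fires
  mt2 <- model_spec(N = 1, beta = 1, drive = -0.1,
                    gamma_law = gamma_point(0), dynamics_kind = "theta")
  tr2 <- simulate_network(mt2, seed = 1, T = 30, mode = "fixed_step",
                          dt = 1e-3, init = list(phases = 0, gammas = 0,
                                                 u0 = 0))
  expect_equal(nrow(tr2$spikes), 0L)
  # event-driven mode refuses theta dynamics
  expect_error(simulate_network(mt, seed = 1, T = 1, mode = "event_driven"),
               "linear_phase")
})

test_that("event-driven mode enforces its monotone-crossing preconditions", {
  md <- model_spec(N = 5, beta = 1,
                   drive = drive_tabulated(c(0, 1), c(1, 2)))
  expect_error(simulate_network(md, seed = 1, T = 1), "constant")
  mneg <- model_spec(N = 5, beta = 1, drive = -1)
  expect_error(simulate_network(mneg, seed = 1, T = 1), "fixed_step")
  # but fixed-step handles the tabulated drive
  tr <- simulate_network(md, seed = 1, T = 2, mode = "fixed_step", dt = 1e-3)
  expect_true(all(is.finite(tr$u_series)))
})
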