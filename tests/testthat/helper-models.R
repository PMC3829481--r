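# shared model fixtures, built in code

uncoupled_model <- function(N = 100, beta = 2, I = 1, u0 = 0) {
  model_spec(N = N, beta = beta, drive = I, gamma_law = gamma_point(0),
             u0 = u0, rho0 = rho_uniform())
}

coupled_model <- function(N = 200, gbar = 0.5, beta = 1, I = 1,
                          rho0 = rho_uniform()) {
  model_spec(N = N, beta = beta, drive = I, gamma_law = gamma_point(gbar),
             rho0 = rho0)
}

grid_for <- function(model, M = 64) phase_grid(M, model$gamma_law)

# closed-form ensemble mean of the drive for uncoupled uniform oscillators:
# E u(t) = u0 e^{-beta t} + (I / 2 pi)(1 - e^{-beta t})
uncoupled_mean_u <- function(t, beta, I, u0 = 0) {
  u0 * exp(-beta * t) + (I / (2 * pi)) * (1 - exp(-beta * t))
}

# independent oracle for the uncoupled covariances: with gamma = 0 every
# neuron fires deterministically from its initial phase, so
# u(t) = u0 e^{-beta t} + (beta / N) sum_i h_t(theta0_i) with
# h_t(theta0) = sum over past spike times of e^{-beta (t - tau)}; moments
# over theta0 ~ U[-pi, pi) follow by quadrature
uncoupled_oracle <- function(t, beta, I, n = 20001) {
  th0 <- seq(-pi, pi, length.out = n + 1)[seq_len(n)]
  tau1 <- (pi - th0) / I
  P <- 2 * pi / I
  h <- vapply(seq_len(n), function(i) {
    if (tau1[i] > t) return(0)
    ks <- 0:floor((t - tau1[i]) / P)
    sum(exp(-beta * (t - tau1[i] - ks * P)))
  }, numeric(1))
  list(mean_u = beta * mean(h),
       C11 = beta^2 * (mean(h^2) - mean(h)^2))
}
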