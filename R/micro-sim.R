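#' Draw the random initial state of a network
#'
#' Phases are i.i.d. from rho0 and coupling coefficients i.i.d. from
#' g(gamma), independently across neurons, matching the product-form initial
#' ensemble over which all moment quantities are defined. Deterministic given
#' the seed (R's default RNG).
#'
#' @param model a [model_spec()].
#' @param seed integer RNG seed.
#' @return list with `phases` (N angles in \[-pi, pi)), `gammas` (N coupling
#'   values) and `u0`.
#' @export
draw_initial_state <- function(model, seed) {
  stopifnot(inherits(model, "model_spec"))
  set.seed(as.integer(seed))
  N <- model$N
  law <- model$rho0
  phases <- switch(law$kind,
    uniform = stats::runif(N, -pi, pi),
    bump = sample_von_mises(N, law$center, law$concentration),
    tabulated = sample_tabulated(N, law),
    stop("unknown rho0 law kind: ", law$kind, call. = FALSE)
  )
  gl <- model$gamma_law
  gammas <- if (length(gl$nodes) == 1L) {
    rep(gl$nodes, N)
  } else {
    gl$nodes[sample.int(length(gl$nodes), N, replace = TRUE, prob = gl$weights)]
  }
  list(phases = wrap_angle(phases), gammas = gammas, u0 = model$u0)
}

# von Mises sampling by rejection from a uniform proposal; the acceptance
# rate is 2*pi*f_max ~ exp(kappa)/I0(kappa), adequate for moderate kappa
sample_von_mises <- function(n, mu, kappa) {
  fmax <- exp(kappa) / (2 * pi * besselI(kappa, 0))
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 2 * pi * fmax * 1.1) + 16L
    x <- stats::runif(m, -pi, pi)
    y <- stats::runif(m, 0, fmax)
    dens <- exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0))
    out <- c(out, x[y < dens])
  }
  mu0 <- out[seq_len(n)]
  mu0
}

# inverse-CDF sampling from a periodic tabulated density, refined onto a
# dense grid by the periodic spline interpolant
sample_tabulated <- function(n, law) {
  f <- rho0_interpolant(law)
  grid <- seq(-pi, pi, length.out = 4097L)
  dens <- pmax(f(grid), 0)
  cdf <- cumsum(c(0, diff(grid) * (dens[-1] + dens[-length(dens)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  stats::approx(cdf, grid, xout = u, ties = "ordered")$y
}

#' Closed-form synaptic drive propagation between events
#'
#' Between spikes the shared drive decays exponentially; this returns its
#' value after `delta_t` and its time integral over the interval,
#' u = u_k exp(-beta dt) and int u = u_k (1 - exp(-beta dt))/beta.
#'
#' @param u_k drive value at the start of the interval.
#' @param beta decay rate.
#' @param delta_t interval length (>= 0).
#' @return list with `u` and `integral_u`.
#' @examples
#' drive_between_events(1, beta = 2, delta_t = 1)
#' @export
drive_between_events <- function(u_k, beta, delta_t) {
  stopifnot(delta_t >= 0, beta > 0)
  list(u = u_k * exp(-beta * delta_t),
       integral_u = u_k * (-expm1(-beta * delta_t)) / beta)
}

#' Simulate one realization of the N-neuron network
#'
#' Integrates the coupled system dtheta_i/dt = F(theta_i, gamma_i, u),
#' du/dt = -beta u + beta nu(t) with nu the population delta train: each
#' crossing of the firing phase pi wraps the phase by -2 pi, records a spike
#' and kicks u upward by exactly beta/N.
#'
#' `event_driven` mode (linear_phase dynamics, constant nonnegative external
#' drive, nonnegative gamma nodes) is exact up to the crossing-time root
#' tolerance (1e-12 time units): between spikes u is an exact exponential and
#' every phase advance has a closed form. `fixed_step` mode supports both
#' dynamics kinds: within a step u decays exactly, phases advance in closed
#' form (linear_phase) or by classical RK4 (theta), and crossings are located
#' inside the step with each spike's exponential contribution superposed.
#'
#' @param model a [model_spec()] (must have `dynamics_kind = "linear_phase"`
#'   for event-driven mode).
#' @param seed integer seed for the initial state.
#' @param T duration (> 0).
#' @param mode `"event_driven"` or `"fixed_step"`.
#' @param dt_record sampling interval for the recorded drive series (ignored
#'   when `sample_times` is given).
#' @param sample_times optional explicit output times in \[0, T\].
#' @param dt fixed-step integrator step (fixed_step mode).
#' @param record_spikes,record_phases toggles for the spike list and the
#'   per-sample phase snapshots.
#' @param init optional pre-drawn initial state (as from
#'   [draw_initial_state()]); when given, `seed` is only stored.
#' @return an object of class `micro_trajectory`: `sample_times`, `u_series`,
#'   `spikes` (data.frame neuron/time, sorted by time), optional
#'   `phase_snapshots` (S x N), `n_events`, `u_final`, `seed`, `model`.
#' @examples
#' m <- model_spec(N = 1, beta = 1, drive = 1, gamma_law = gamma_point(0))
#' tr <- simulate_network(m, seed = 1, T = 4,
#'                        init = list(phases = 0, gammas = 0, u0 = 0))
#' tr$spikes$time[1] # pi: unit speed over distance pi
#' @export
simulate_network <- function(model, seed, T,
                             mode = c("event_driven", "fixed_step"),
                             dt_record = 0.1, sample_times = NULL,
                             dt = 1e-3, record_spikes = TRUE,
                             record_phases = FALSE, init = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "model_spec"))
  if (!is.numeric(T) || length(T) != 1L || T <= 0) {
    stop("T must be a positive duration", call. = FALSE)
  }
  if (is.null(sample_times)) {
    sample_times <- seq(0, T, by = dt_record)
  }
  sample_times <- sort(as.numeric(sample_times))
  if (any(sample_times < 0) || any(sample_times > T + 1e-12)) {
    stop("sample_times must lie in [0, T]", call. = FALSE)
  }
  if (is.null(init)) init <- draw_initial_state(model, seed)

  if (mode == "event_driven") {
    if (model$dynamics_kind != "linear_phase") {
      stop("event_driven mode requires dynamics_kind = 'linear_phase'",
           call. = FALSE)
    }
    if (model$drive$kind != "constant") {
      stop("event_driven mode requires a constant external drive; ",
           "use mode = 'fixed_step' for tabulated I(t)", call. = FALSE)
    }
    if (model$drive$value < 0 || any(model$gamma_law$nodes < 0)) {
      stop("event_driven mode requires I >= 0 and nonnegative gamma nodes ",
           "(monotone crossings); use mode = 'fixed_step'", call. = FALSE)
    }
    raw <- .sim_event_driven(init$phases, init$gammas, init$u0, model$beta,
                             model$drive$value, T, sample_times,
                             record_spikes, record_phases)
  } else {
    if (model$drive$kind == "constant") {
      dtr <- 0; dvr <- model$drive$value
    } else {
      dtr <- model$drive$time; dvr <- model$drive$values
    }
    raw <- .sim_fixed_step(init$phases, init$gammas, init$u0, model$beta,
                           dtr, dvr, model$drive$kind == "constant",
                           if (model$dynamics_kind == "linear_phase") 0L
                           else 1L,
                           dt, T, sample_times, record_spikes, record_phases)
  }

  spikes <- data.frame(neuron = as.integer(raw$spike_id),
                       time = as.numeric(raw$spike_time))
  structure(list(
    sample_times = sample_times,
    u_series = as.numeric(raw$u),
    spikes = spikes,
    phase_snapshots = if (record_phases) raw$phases else NULL,
    n_events = raw$n_events,
    u_final = raw$u_final,
    seed = seed,
    mode = mode,
    model = model
  ), class = "micro_trajectory")
}

#' @export
print.micro_trajectory <- function(x, ...) {
  cat(sprintf(
    "<micro_trajectory> N = %d, %s, %d spike event(s), %d sample time(s)\n",
    x$model$N, x$mode, as.integer(x$n_events), length(x$sample_times)))
  invisible(x)
}
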