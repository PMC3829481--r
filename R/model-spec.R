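#' Coupling-parameter laws g(gamma)
#'
#' The per-neuron coupling coefficient gamma multiplies the shared synaptic
#' drive u in the phase-velocity law. Its population distribution g(gamma) is
#' always represented internally as quadrature nodes plus weights, so that
#' every gamma-integral in the moment equations becomes a finite weighted sum:
#' a point mass is one node, a finite mixture is several, and a continuous
#' density is approximated by user-supplied quadrature nodes and weights.
#'
#' @param gbar location of the point mass.
#' @param nodes numeric vector of gamma values.
#' @param weights matching nonnegative weights summing to 1.
#' @return an object of class `gamma_law` with elements `nodes` and `weights`.
#' @examples
#' gamma_point(0.5)
#' gamma_mixture(c(0, 1), c(0.25, 0.75))
#' @export
gamma_point <- function(gbar) {
  new_gamma_law(gbar, 1, "point")
}

#' @rdname gamma_point
#' @export
gamma_mixture <- function(nodes, weights) {
  new_gamma_law(nodes, weights, "mixture")
}

#' @rdname gamma_point
#' @export
gamma_quadrature <- function(nodes, weights) {
  new_gamma_law(nodes, weights, "quadrature")
}

new_gamma_law <- function(nodes, weights, kind) {
  stopifnot(is.numeric(nodes), is.numeric(weights),
            length(nodes) == length(weights), length(nodes) >= 1L)
  if (any(weights < 0)) {
    stop("gamma_law weights must be nonnegative", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("gamma_law weights must sum to 1 (within 1e-12)", call. = FALSE)
  }
  structure(list(nodes = as.numeric(nodes), weights = as.numeric(weights),
                 kind = kind),
            class = "gamma_law")
}

#' @export
print.gamma_law <- function(x, ...) {
  cat("<gamma_law:", x$kind, ">\n")
  print(data.frame(gamma = x$nodes, weight = x$weights))
  invisible(x)
}

gamma_mean <- function(law) sum(law$weights * law$nodes)

#' Initial phase-density laws rho0(theta)
#'
#' The initial phase of every neuron is drawn independently from rho0 on the
#' periodic domain \[-pi, pi), the same law for every gamma. `rho_uniform` is
#' the asynchronous state 1/(2*pi); `rho_bump` is a wrapped (von Mises) bump
#' exp(kappa*cos(theta - center)) / (2*pi*I0(kappa)); `rho_tabulated` takes a
#' nonnegative table on a theta grid, which must integrate to 1 (trapezoid on
#' its own grid, periodic) within 1e-10, and is evaluated elsewhere by
#' periodic cubic-spline interpolation.
#'
#' @param center bump center (radians).
#' @param concentration von Mises concentration kappa (> 0).
#' @param theta increasing grid of angles in \[-pi, pi).
#' @param values matching nonnegative density values.
#' @return an object of class `rho0_law`.
#' @examples
#' rho_uniform()
#' rho_bump(center = 0, concentration = 2)
#' @export
rho_uniform <- function() {
  structure(list(kind = "uniform"), class = "rho0_law")
}

#' @rdname rho_uniform
#' @export
rho_bump <- function(center = 0, concentration = 1) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(concentration), length(concentration) == 1L,
            concentration > 0)
  structure(list(kind = "bump", center = as.numeric(center),
                 concentration = as.numeric(concentration)),
            class = "rho0_law")
}

#' @rdname rho_uniform
#' @export
rho_tabulated <- function(theta, values) {
  stopifnot(is.numeric(theta), is.numeric(values),
            length(theta) == length(values), length(theta) >= 4L)
  if (is.unsorted(theta, strictly = TRUE)) {
    stop("rho_tabulated: theta grid must be strictly increasing", call. = FALSE)
  }
  if (min(theta) < -pi || max(theta) >= pi) {
    stop("rho_tabulated: theta grid must lie in [-pi, pi)", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("rho_tabulated: density values must be nonnegative", call. = FALSE)
  }
  # periodic trapezoid: close the circle with the wrap-around panel
  th <- c(theta, theta[1] + 2 * pi)
  v <- c(values, values[1])
  total <- sum(diff(th) * (v[-1] + v[-length(v)]) / 2)
  if (abs(total - 1) > 1e-10) {
    stop(sprintf(
      "rho_tabulated: density must integrate to 1 over [-pi, pi); got %.12g",
      total), call. = FALSE)
  }
  structure(list(kind = "tabulated", theta = as.numeric(theta),
                 values = as.numeric(values)),
            class = "rho0_law")
}

#' Evaluate an initial phase density
#'
#' Evaluates rho0 at arbitrary angles, wrapping into \[-pi, pi). Tabulated
#' laws use periodic cubic-spline interpolation, clipped at zero.
#'
#' @param law a [rho_uniform()], [rho_bump()] or [rho_tabulated()] object.
#' @param theta numeric vector of angles.
#' @return density values, same length as `theta`.
#' @export
rho0_density <- function(law, theta) {
  th <- wrap_angle(theta)
  switch(law$kind,
    uniform = rep(1 / (2 * pi), length(th)),
    bump = {
      k <- law$concentration
      exp(k * cos(th - law$center)) / (2 * pi * besselI(k, 0))
    },
    tabulated = {
      f <- rho0_interpolant(law)
      pmax(f(th), 0)
    },
    stop("unknown rho0 law kind: ", law$kind, call. = FALSE)
  )
}

rho0_interpolant <- function(law) {
  # periodic cubic spline through the table; splinefun(method = "periodic")
  # needs matching first/last ordinates, so append the wrapped first point
  th <- c(law$theta, law$theta[1] + 2 * pi)
  v <- c(law$values, law$values[1])
  f <- stats::splinefun(th, v, method = "periodic")
  t0 <- law$theta[1]
  function(x) f(t0 + (x - t0) %% (2 * pi))
}

#' External drive specifications I(t)
#'
#' The external drive is either a constant or a tabulated time series with
#' piecewise-linear interpolation (held constant beyond the table ends).
#'
#' @param value constant drive value.
#' @param time increasing time knots.
#' @param values drive values at the knots.
#' @return an object of class `drive_spec`.
#' @export
drive_constant <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(kind = "constant", value = as.numeric(value)),
            class = "drive_spec")
}

#' @rdname drive_constant
#' @export
drive_tabulated <- function(time, values) {
  stopifnot(is.numeric(time), is.numeric(values),
            length(time) == length(values), length(time) >= 2L)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("drive_tabulated: time knots must be strictly increasing",
         call. = FALSE)
  }
  structure(list(kind = "tabulated", time = as.numeric(time),
                 values = as.numeric(values)),
            class = "drive_spec")
}

#' Evaluate the external drive at given times
#' @param drive a `drive_spec`.
#' @param t numeric vector of times.
#' @return drive values.
#' @export
drive_value <- function(drive, t) {
  if (drive$kind == "constant") return(rep(drive$value, length(t)))
  tt <- pmin(pmax(t, drive$time[1]), drive$time[length(drive$time)])
  stats::approx(drive$time, drive$values, xout = tt, rule = 2)$y
}

#' Network/model definition
#'
#' Bundles everything that defines one network: the neuron count N, the
#' synaptic decay rate beta of the shared drive u (du/dt = -beta*u + beta*nu),
#' the external drive I(t), the coupling-parameter law g(gamma), the phase
#' velocity family (`linear_phase`: F = I + gamma*u; `theta`: the theta-neuron
#' law F = 1 - cos(theta) + (1 + cos(theta))(I + gamma*u)), the initial drive
#' u0, and the initial phase-density law rho0. A neuron spikes when its phase
#' crosses pi (identified with -pi).
#'
#' @param N positive integer neuron count.
#' @param beta synaptic decay rate (> 0, units 1/time).
#' @param drive a `drive_spec`, or a single number (taken as constant drive).
#' @param gamma_law a `gamma_law` object.
#' @param dynamics_kind `"linear_phase"` or `"theta"`.
#' @param u0 initial synaptic drive.
#' @param rho0 a `rho0_law` object.
#' @return an object of class `model_spec`.
#' @examples
#' m <- model_spec(N = 100, beta = 1, drive = 1, gamma_law = gamma_point(0.5))
#' m
#' @export
model_spec <- function(N, beta, drive, gamma_law = gamma_point(0),
                       dynamics_kind = c("linear_phase", "theta"),
                       u0 = 0, rho0 = rho_uniform()) {
  dynamics_kind <- match.arg(dynamics_kind)
  if (is.numeric(drive)) drive <- drive_constant(drive)
  stopifnot(inherits(drive, "drive_spec"), inherits(gamma_law, "gamma_law"),
            inherits(rho0, "rho0_law"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be a positive integer", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("beta must be a positive rate", call. = FALSE)
  }
  stopifnot(is.numeric(u0), length(u0) == 1L, is.finite(u0))
  structure(list(N = N, beta = as.numeric(beta), drive = drive,
                 gamma_law = gamma_law, dynamics_kind = dynamics_kind,
                 u0 = as.numeric(u0), rho0 = rho0),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n")
  cat(sprintf("  N = %d, beta = %g, u0 = %g, dynamics = %s\n",
              x$N, x$beta, x$u0, x$dynamics_kind))
  if (x$drive$kind == "constant") {
    cat(sprintf("  drive: constant I = %g\n", x$drive$value))
  } else {
    cat(sprintf("  drive: tabulated on %d knots over [%g, %g]\n",
                length(x$drive$time), min(x$drive$time), max(x$drive$time)))
  }
  cat(sprintf("  g(gamma): %s with %d node(s), mean gamma = %g\n",
              x$gamma_law$kind, length(x$gamma_law$nodes),
              gamma_mean(x$gamma_law)))
  cat(sprintf("  rho0: %s\n", x$rho0$kind))
  invisible(x)
}

#' Phase-velocity law F(theta, gamma, u)
#'
#' The phase speed of one neuron given its phase, its coupling coefficient,
#' the current shared drive u and external drive I. For `linear_phase` the
#' speed is F = I + gamma*u, independent of theta; for `theta` it is the
#' theta-neuron law F = 1 - cos(theta) + (1 + cos(theta))*(I + gamma*u),
#' 2*pi-periodic in theta and equal to 2 exactly at the firing phase pi.
#'
#' @param theta phase angle(s).
#' @param gamma coupling coefficient(s).
#' @param u shared synaptic drive value.
#' @param I external drive value.
#' @param kind `"linear_phase"` or `"theta"`.
#' @return phase speed(s), recycled to the common length.
#' @examples
#' velocity(0.3, gamma = 0, u = 7, I = 1.5, kind = "linear_phase") # 1.5
#' velocity(pi, gamma = 2, u = 3, I = -1, kind = "theta")          # 2
#' @export
velocity <- function(theta, gamma, u, I, kind = c("linear_phase", "theta")) {
  kind <- match.arg(kind)
  base <- I + gamma * u
  switch(kind,
    linear_phase = base + 0 * theta,
    theta = 1 - cos(theta) + (1 + cos(theta)) * base
  )
}

#' Wrap angles into \[-pi, pi)
#' @param theta numeric vector of angles.
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  theta - 2 * pi * floor((theta + pi) / (2 * pi))
}
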