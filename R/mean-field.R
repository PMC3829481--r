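#' Solve the N -> infinity mean-field system
#'
#' In the infinite-network limit the empirical phase density becomes a smooth
#' density a3(theta, gamma, t) obeying the Vlasov advection equation
#' `da3/dt + d/dtheta[F a3] = 0` while the mean drive a1 obeys
#' `da1/dt = -beta a1 + beta * integral dgamma F(pi, gamma, a1) a3(pi, gamma, t)`.
#'
#' For `linear_phase` dynamics the advection speed I + gamma a1 is
#' theta-independent, so each gamma-slice of the density is a rigid rotation
#' of rho0 by Phi_gamma(t) = int I + gamma * int a1: the default
#' `characteristics` method advances (a1, int a1) with a classical RK4 step,
#' evaluating the density at the firing phase through the (exact or periodic
#' cubic spline) rho0 evaluator at the shifted angle — no grid transport and
#' no numerical diffusion. `grid_advection` steps the density on the grid
#' with the same Strang-split semi-Lagrangian core used by [solve_gae()]
#' (linear_phase), or a first-order conservative upwind scheme for the
#' theta model, whose speed depends on theta.
#'
#' @param model a [model_spec()].
#' @param grid a [phase_grid()] (its gamma nodes must match the model's law).
#' @param T duration.
#' @param dt time step.
#' @param method `"characteristics"` (default, linear_phase only),
#'   `"grid_advection"`, or `"wilson_cowan"` (uniform rho0 only).
#' @param snapshot_times times at which the density field is stored
#'   (default: c(0, T)).
#' @return an object of class `mean_field_solution`: `times`, `a1_series`,
#'   `snapshot_times`, `a3_fields` (list of M x Q matrices), `method`.
#' @examples
#' m <- model_spec(N = 100, beta = 2, drive = 1, gamma_law = gamma_point(0))
#' sol <- solve_mean_field(m, phase_grid(32, gamma_point(0)), T = 2, dt = 1e-3)
#' max(abs(sol$a1_series - (1 - exp(-2 * sol$times)) / (2 * pi)))
#' @export
solve_mean_field <- function(model, grid, T, dt,
                             method = c("characteristics", "grid_advection",
                                        "wilson_cowan"),
                             snapshot_times = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "model_spec"), inherits(grid, "phase_grid"))
  check_grid_gamma(model, grid)
  if (is.null(snapshot_times)) snapshot_times <- c(0, T)

  if (method == "wilson_cowan") {
    a1 <- wilson_cowan_reduced(model, T, dt)
    times <- attr(a1, "times")
    a3 <- rho0_on_grid(model$rho0, grid)
    return(new_mean_field_solution(times, as.numeric(a1), snapshot_times,
                                   rep(list(a3), length(snapshot_times)),
                                   method))
  }

  if (method == "characteristics") {
    if (model$dynamics_kind != "linear_phase") {
      stop("characteristics method requires linear_phase dynamics ",
           "(theta-independent advection speed); ",
           "use method = 'grid_advection'", call. = FALSE)
    }
    return(mean_field_characteristics(model, grid, T, dt, snapshot_times))
  }

  if (model$dynamics_kind == "linear_phase") {
    sol <- solve_gae(model, grid, T, dt, snapshot_times = snapshot_times,
                     fluctuation_terms = FALSE)
    return(new_mean_field_solution(sol$times, sol$a1_series, sol$snapshot_times,
                                   lapply(sol$snapshots, `[[`, "a3"),
                                   "grid_advection"))
  }
  mean_field_upwind_theta(model, grid, T, dt, snapshot_times)
}

new_mean_field_solution <- function(times, a1, snapshot_times, a3_fields,
                                    method) {
  structure(list(times = times, a1_series = a1,
                 snapshot_times = snapshot_times, a3_fields = a3_fields,
                 method = method),
            class = "mean_field_solution")
}

#' @export
print.mean_field_solution <- function(x, ...) {
  cat(sprintf(
    "<mean_field_solution> method = %s, %d times, a1(T) = %.6g\n",
    x$method, length(x$times), x$a1_series[length(x$a1_series)]))
  invisible(x)
}

check_grid_gamma <- function(model, grid) {
  gl <- model$gamma_law
  if (length(gl$nodes) != length(grid$gamma_nodes) ||
      any(abs(gl$nodes - grid$gamma_nodes) > 1e-12) ||
      any(abs(gl$weights - grid$gamma_weights) > 1e-12)) {
    stop("grid gamma quadrature does not match the model's gamma_law",
         call. = FALSE)
  }
  invisible(TRUE)
}

# characteristics solver: state (a1, J = int_0^t a1), classical RK4;
# the density at the firing phase is rho0 evaluated at pi - Phi_gamma
mean_field_characteristics <- function(model, grid, T, dt, snapshot_times) {
  beta <- model$beta
  gam <- grid$gamma_nodes
  w <- grid$gamma_weights
  rho_at <- if (model$rho0$kind == "tabulated") {
    rho0_interpolant(model$rho0)
  } else {
    function(x) rho0_density(model$rho0, x)
  }
  Iint <- drive_integral_fun(model$drive)

  deriv <- function(t, a1, J) {
    Iv <- drive_value(model$drive, t)
    shift <- Iint(t) + gam * J
    dens_pi <- pmax(rho_at(wrap_angle(pi - shift)), 0)
    c(-beta * a1 + beta * sum(w * (Iv + gam * a1) * dens_pi), a1)
  }

  nsteps <- ceiling(T / dt - 1e-9)
  times <- c(0, dt * seq_len(nsteps))
  times[length(times)] <- min(times[length(times)], T)
  a1s <- numeric(length(times))
  a1 <- model$u0; J <- 0
  a1s[1] <- a1
  snaps <- vector("list", length(snapshot_times))
  snap_state <- function(t, J) {
    shift <- outer(rep(1, grid$M), Iint(t) + gam * J)
    th <- matrix(grid$theta_nodes, grid$M, length(gam)) - shift
    matrix(pmax(rho_at(wrap_angle(th)), 0), grid$M, length(gam))
  }
  si <- 1L
  while (si <= length(snapshot_times) && snapshot_times[si] <= 0) {
    snaps[[si]] <- snap_state(0, J); si <- si + 1L
  }
  for (k in seq_len(nsteps)) {
    t0 <- times[k]; h <- times[k + 1] - times[k]
    k1 <- deriv(t0, a1, J)
    k2 <- deriv(t0 + h / 2, a1 + h / 2 * k1[1], J + h / 2 * k1[2])
    k3 <- deriv(t0 + h / 2, a1 + h / 2 * k2[1], J + h / 2 * k2[2])
    k4 <- deriv(t0 + h, a1 + h * k3[1], J + h * k3[2])
    a1 <- a1 + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    J <- J + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    a1s[k + 1] <- a1
    while (si <= length(snapshot_times) &&
           snapshot_times[si] <= times[k + 1] + 1e-12) {
      snaps[[si]] <- snap_state(times[k + 1], J); si <- si + 1L
    }
  }
  new_mean_field_solution(times, a1s, snapshot_times[seq_len(si - 1L)],
                          snaps[seq_len(si - 1L)], "characteristics")
}

# cumulative integral int_0^t I(s) ds of the external drive (piecewise-linear
# interpolation inside the table, constant extension beyond its ends)
drive_integral_fun <- function(drive) {
  if (drive$kind == "constant") {
    I0 <- drive$value
    return(function(t) I0 * t)
  }
  tt <- drive$time; vv <- drive$values
  n <- length(tt)
  cum <- c(0, cumsum(diff(tt) * (vv[-1] + vv[-n]) / 2))
  slope <- diff(vv) / diff(tt)
  from_first <- function(s) {
    # integral from tt[1] to s, s >= tt[1]
    if (s >= tt[n]) return(cum[n] + vv[n] * (s - tt[n]))
    i <- findInterval(s, tt)
    ds <- s - tt[i]
    cum[i] + vv[i] * ds + 0.5 * slope[i] * ds^2
  }
  anchor <- function(s) {
    # integral from min(tt[1], 0) to s, with constant extension before tt[1]
    if (s <= tt[1]) return(vv[1] * (s - min(tt[1], 0)))
    vv[1] * (tt[1] - min(tt[1], 0)) + from_first(s)
  }
  function(t) vapply(t, function(s) anchor(s) - anchor(0), numeric(1))
}

#' Wilson-Cowan reduction of the mean-field system
#'
#' For neurons initially distributed uniformly in phase, the density stays
#' uniform under the theta-independent advection and the mean-field system
#' collapses to a single rate ODE,
#' `da1/dt = -beta a1 + (beta/2 pi) (I + gbar a1)`, with gbar the mean of
#' g(gamma) — a Wilson-Cowan equation whose gain is (beta/2 pi)(I + gbar a1).
#' For any other initial density the full phase-conservation equation must be
#' kept and this reduction refuses to run. Integration is by
#' `deSolve::ode(method = "rk4")` on the same step grid as
#' [solve_mean_field()], which provides an independent route for the
#' structural-equivalence check between the two solvers.
#'
#' @param model a [model_spec()] with uniform rho0.
#' @param T duration.
#' @param dt step.
#' @return numeric vector of a1 values with attribute `times`.
#' @examples
#' m <- model_spec(N = 100, beta = 2, drive = 1, gamma_law = gamma_point(0))
#' a1 <- wilson_cowan_reduced(m, T = 1, dt = 1e-3)
#' a1[length(a1)] # ~ (1 - exp(-2)) / (2*pi)
#' @export
wilson_cowan_reduced <- function(model, T, dt) {
  stopifnot(inherits(model, "model_spec"))
  if (model$rho0$kind != "uniform") {
    stop("wilson_cowan_reduced is only valid for a uniform initial phase ",
         "density; for any other initial condition the phase conservation ",
         "equation must be included (use solve_mean_field)", call. = FALSE)
  }
  if (model$dynamics_kind != "linear_phase") {
    stop("wilson_cowan_reduced requires linear_phase dynamics", call. = FALSE)
  }
  beta <- model$beta
  gbar <- gamma_mean(model$gamma_law)
  nsteps <- ceiling(T / dt - 1e-9)
  times <- c(0, dt * seq_len(nsteps))
  times[length(times)] <- min(times[length(times)], T)
  rhs <- function(t, y, parms) {
    Iv <- drive_value(model$drive, t)
    list(-beta * y[1] + beta / (2 * pi) * (Iv + gbar * y[1]))
  }
  out <- deSolve::ode(y = c(a1 = model$u0), times = times, func = rhs,
                      parms = NULL, method = "rk4")
  a1 <- as.numeric(out[, "a1"])
  attr(a1, "times") <- times
  a1
}

# first-order conservative upwind fallback for theta-model dynamics, whose
# advection speed F(theta) = 1 - cos + (1 + cos)(I + gamma a1) depends on
# theta; nonnegative for I + gamma*a1 >= 0, so the upwind direction is fixed
mean_field_upwind_theta <- function(model, grid, T, dt, snapshot_times) {
  beta <- model$beta
  M <- grid$M; gam <- grid$gamma_nodes; w <- grid$gamma_weights
  a3 <- rho0_on_grid(model$rho0, grid)
  a1 <- model$u0
  # speeds at cell edges theta_{m+1/2}
  edges <- grid$theta_nodes + grid$dtheta / 2
  nsteps <- ceiling(T / dt - 1e-9)
  times <- c(0, dt * seq_len(nsteps))
  a1s <- numeric(length(times)); a1s[1] <- a1
  snaps <- vector("list", length(snapshot_times)); si <- 1L
  while (si <= length(snapshot_times) && snapshot_times[si] <= 0) {
    snaps[[si]] <- a3; si <- si + 1L
  }
  for (k in seq_len(nsteps)) {
    t0 <- times[k]; h <- times[k + 1] - times[k]
    Iv <- drive_value(model$drive, t0)
    Fedge <- vapply(gam, function(g) velocity(edges, g, a1, Iv, "theta"),
                    numeric(M))
    if (max(Fedge) * h > grid$dtheta) {
      stop(sprintf(
        "upwind CFL violated: max|F| dt = %.3g > dtheta = %.3g; reduce dt",
        max(Fedge) * h, grid$dtheta), call. = FALSE)
    }
    flux <- Fedge * a3                        # upwind for F >= 0
    div <- (flux - flux[c(M, 1:(M - 1)), , drop = FALSE]) / grid$dtheta
    nu <- sum(w * 2 * a3[grid$firing_node, ]) # F(pi, .) = 2 exactly
    a3 <- a3 - h * div
    a1 <- a1 + h * (-beta * a1 + beta * nu)
    a1s[k + 1] <- a1
    while (si <= length(snapshot_times) &&
           snapshot_times[si] <= times[k + 1] + 1e-12) {
      snaps[[si]] <- a3; si <- si + 1L
    }
  }
  new_mean_field_solution(times, a1s, snapshot_times[seq_len(si - 1L)],
                          snaps[seq_len(si - 1L)], "grid_advection")
}
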