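#' Initialize the moment state for the generalized activity equations
#'
#' The order-1/N moment closure propagates the mean drive a1, the mean phase
#' density a3(theta, gamma), the equal-time drive-density cross covariance
#' C(theta, gamma) = N Cov(u, eta), the N-scaled drive variance
#' C11 = N Var(u), and the equal-time two-point density covariance
#' C33(x; x') = N Cov(eta(x), eta(x')). With every neuron drawn independently
#' from rho0 and a deterministic u0, the initial state is a1 = u0, a3 = rho0,
#' C = 0, C11 = 0, and C33 equal to the i.i.d.-draw (multinomial) density
#' covariance.
#'
#' Two cumulant conventions are supported for C33. `ordinary` is the raw
#' density covariance, delta_grid(x - x') rho0(x) - rho0(x) rho0(x'), whose
#' diagonal self-overlap term carries mass 1/(dtheta w_q) per node; its rows
#' integrate to zero because the total density is fixed at 1 in every
#' realization. `factorial` (normal-ordered) subtracts the self-overlap term,
#' leaving the smooth -rho0(x) rho0(x').
#'
#' @param model a [model_spec()].
#' @param grid a [phase_grid()] matching the model's gamma law.
#' @param convention `"ordinary"` (default, see [solve_gae()]) or
#'   `"factorial"`.
#' @return an object of class `moment_state` with fields `t`, `a1`, `a3`
#'   (M x Q), `C` (M x Q), `C11`, `C33` ((M*Q) x (M*Q), theta fastest), `N`,
#'   `convention`, `grid`.
#' @export
init_moments <- function(model, grid,
                         convention = c("ordinary", "factorial")) {
  convention <- match.arg(convention)
  stopifnot(inherits(model, "model_spec"), inherits(grid, "phase_grid"))
  check_grid_gamma(model, grid)
  a3 <- rho0_on_grid(model$rho0, grid)
  rho_flat <- as.vector(a3)
  C33 <- -outer(rho_flat, rho_flat)
  if (convention == "ordinary") {
    C33 <- C33 + diag(rho_flat / self_delta_measure(grid), nrow = length(rho_flat))
  }
  new_moment_state(t = 0, a1 = model$u0, a3 = a3,
                   C = matrix(0, grid$M, length(grid$gamma_nodes)),
                   C11 = 0, C33 = C33, N = model$N,
                   convention = convention, grid = grid)
}

# measure of one grid cell per flattened node: dtheta * w_q
self_delta_measure <- function(grid) {
  rep(grid$dtheta * grid$gamma_weights, each = grid$M)
}

new_moment_state <- function(t, a1, a3, C, C11, C33, N, convention, grid) {
  structure(list(t = t, a1 = a1, a3 = a3, C = C, C11 = C11, C33 = C33,
                 N = N, convention = convention, grid = grid),
            class = "moment_state")
}

#' @export
print.moment_state <- function(x, ...) {
  cat(sprintf(
    "<moment_state> t = %g (%s cumulants): a1 = %.6g, C11 = %.6g\n",
    x$t, x$convention, x$a1, x$C11))
  cat(sprintf("  grid M = %d x %d gamma node(s); integral a3 = %.8g\n",
              x$grid$M, length(x$grid$gamma_nodes),
              grid_integral(x$a3, x$grid)))
  invisible(x)
}

# ---- internal stepping core ------------------------------------------------
# The smooth two-point field S is the factorial part of C33: under the
# ordinary convention the diagonal self-term delta(x - x') a3(x) is carried
# analytically (it advects rigidly with a3 at leading order) and only its
# smooth complement is stepped; its contribution to the cross-covariance
# equation collapses onto the firing node and cancels half of the printed
# firing-line source, leaving net coefficient beta instead of 2 beta.
#
# The cross covariance C carries a maintained jump at the firing line: the
# delta source injects covariance there at rate coeff*beta*F*a3(pi) per unit
# time while advection at speed s = F carries it away, so the one-sided
# limits differ by exactly J = coeff*beta*a3(pi) (the speed cancels). To keep
# the advected field smooth, the jump rides on the fixed sawtooth
# W(theta) = -theta/(2*pi) (unit jump at the line, midpoint zero there, mean
# zero): the state stores the continuous remainder C_reg = C - J*W, whose
# evolution picks up the smooth sources -(dJ/dt + relax*J)*W + s*J/(2*pi)
# while the delta source cancels identically against the transport of J*W.
# Integrals against delta(pi - theta) then sample C at the line as the
# midpoint of the one-sided limits -- which is C_reg at the firing node --
# as delta-function calculus requires.

trail_profile <- function(grid) {
  W <- -grid$theta_nodes / (2 * pi)
  W[grid$firing_node] <- 0           # midpoint of the unit jump at the line
  W
}

# continuous periodic profile with unit slope jump (kink) at the line:
# K(x) = (x - pi)^2 / (4 pi), x the downstream distance from the line;
# together with W it satisfies W + K' = 0 away from the line, which is what
# collapses the jump- and kink-channel sources below
kink_profile <- function(grid) {
  x <- (grid$theta_nodes + pi) %% (2 * pi)
  (x - pi)^2 / (4 * pi)
}

jump_coeff <- function(convention) if (convention == "ordinary") 1 else 2

# slaved singular-channel amplitudes at the firing line: the jump
# J_q = coeff * beta * a3(pi, q) (injection rate over advection speed; the
# speed cancels because F = I + gamma*u is also the advection speed), its
# rate of change via the advective density derivative, and the kink
# kappa_q = (dJ/dt + relax * J)/s (clamped where the speed vanishes,
# in which case the residual stays on the jump channel)
# `a3reg` below is the continuous remainder of the density: at order 1/N the
# mean density itself acquires a jump at the firing line (the delta in
# d/dtheta C injected by the 1/N term of its equation), slaved to
# Ja3 = -(gamma/N) J / s; its firing-node value is the midpoint, which is
# what the rate integral and the C33 self-term consume.
trail_channels <- function(t, a1, a3reg, model, grid, convention) {
  beta <- model$beta
  gam <- grid$gamma_nodes
  w <- grid$gamma_weights
  coeff <- jump_coeff(convention)
  a3pi <- a3reg[grid$firing_node, ]
  s <- drive_value(model$drive, t) + gam * a1
  Da3 <- theta_derivative(a3reg, grid)
  Da3pi <- Da3[grid$firing_node, ]
  J <- coeff * beta * a3pi
  Jdot <- coeff * beta * (-s * Da3pi)
  relax <- beta - beta * sum(w * gam * a3pi)
  target <- Jdot + relax * J
  ok <- abs(s) > 1e-8
  kappa <- ifelse(ok, target / s, 0)
  Ja3 <- ifelse(ok, -(gam / model$N) * J / s, 0)
  list(J = J, Jdot = Jdot, kappa = kappa, resid = target - s * kappa,
       relax = relax, s = s, ok = ok, Ja3 = Ja3, Da3pi = Da3pi,
       D2a3pi = theta_derivative(Da3, grid)[grid$firing_node, ])
}

# time derivative of the kink amplitude kappa = (dJ/dt + relax J)/s along the
# mean-field flow: d2J/dt2 follows from the advective density derivatives at
# the line, and the relaxation coefficient drifts with a3(pi)
trail_kappa_dot <- function(ch, model, grid, convention, da1) {
  beta <- model$beta
  gam <- grid$gamma_nodes
  w <- grid$gamma_weights
  coeff <- jump_coeff(convention)
  sdot <- gam * da1
  Jddot <- coeff * beta * (-sdot * ch$Da3pi + ch$s^2 * ch$D2a3pi)
  relaxdot <- -beta * sum(w * gam * (-ch$s * ch$Da3pi))
  ifelse(abs(ch$s) > 1e-8,
         (Jddot + relaxdot * ch$J + ch$relax * ch$Jdot - ch$kappa * sdot) /
           ch$s,
         0)
}

# conversions between the public fields (with embedded singular channels)
# and the regularized fields the stepper advects; the firing-node values are
# midpoints, so the channel amplitudes are recoverable from either form
reg_to_full <- function(t, y, model, grid, convention) {
  ch <- trail_channels(t, y$a1, y$a3, model, grid, convention)
  W <- trail_profile(grid)
  list(a3 = y$a3 + outer(W, ch$Ja3),
       C = y$Creg + outer(W, ch$J) + outer(kink_profile(grid), ch$kappa))
}

full_to_reg <- function(t, a1, a3, C, model, grid, convention) {
  W <- trail_profile(grid)
  # channel amplitudes depend on the regularized density; the firing-node
  # value is channel-free, and one pass removes the density jump before the
  # derivative-dependent C channels are formed
  ch0 <- trail_channels(t, a1, a3, model, grid, convention)
  a3reg <- a3 - outer(W, ch0$Ja3)
  ch <- trail_channels(t, a1, a3reg, model, grid, convention)
  list(a3 = a3reg,
       Creg = C - outer(W, ch$J) - outer(kink_profile(grid), ch$kappa))
}

strip_self_delta <- function(state) {
  if (state$convention == "ordinary") {
    state$C33 - diag(as.vector(state$a3) / self_delta_measure(state$grid),
                     nrow = length(state$a3))
  } else {
    state$C33
  }
}

add_self_delta <- function(S, a3, grid, convention) {
  if (convention == "ordinary") {
    S + diag(as.vector(a3) / self_delta_measure(grid), nrow = length(a3))
  } else {
    S
  }
}

# time derivatives of all non-advective (source/relaxation) terms; Creg is
# the continuous remainder of the cross covariance (see note above)
gae_source_derivs <- function(t, a1, a3, Creg, C11, S, model, grid, fluct,
                              convention) {
  beta <- model$beta
  N <- model$N
  gam <- grid$gamma_nodes
  w <- grid$gamma_weights
  Iv <- drive_value(model$drive, t)
  a3pi <- a3[grid$firing_node, ]
  Fpi <- Iv + gam * a1
  rate <- sum(w * Fpi * a3pi)

  if (!fluct) {
    return(list(da1 = -beta * a1 + beta * rate,
                da3 = 0, dCreg = 0, dC11 = 0, dS = 0))
  }

  W <- trail_profile(grid)
  K <- kink_profile(grid)
  K0 <- K[grid$firing_node]                   # = pi/4, K is continuous there
  ch <- trail_channels(t, a1, a3, model, grid, convention)
  relax <- ch$relax
  Cpi <- Creg[grid$firing_node, ] + ch$kappa * K0   # midpoint at the line
  Cfull <- Creg + outer(W, ch$J) + outer(K, ch$kappa)

  da1 <- -beta * a1 + beta * rate + (beta / N) * sum(w * gam * Cpi)

  # density update: smooth part of -(gamma/N) dC/dtheta (the sawtooth slope
  # of the jump channel and the kink channel's K' = -W), plus the
  # jump-channel bookkeeping for the density's own 1/N discontinuity
  DCreg <- theta_derivative(Creg, grid)
  sdot <- gam * da1
  Ja3dot <- ifelse(ch$ok,
                   -(gam / N) * (ch$Jdot * ch$s - ch$J * sdot) / ch$s^2, 0)
  da3 <- sweep(DCreg, 2, -gam / N, `*`) +
    outer(W, (gam / N) * ch$kappa) +
    matrix((gam / N) * ch$J / (2 * pi), grid$M, length(gam), byrow = TRUE) -
    outer(W, Ja3dot) +
    matrix(ch$s * ch$Ja3 / (2 * pi), grid$M, length(gam), byrow = TRUE)
  if (any(!ch$ok)) {
    # stalled slice: no advection carries the injected delta away; keep it
    # as grid mass on the firing node
    bad <- which(!ch$ok)
    da3[grid$firing_node, bad] <- da3[grid$firing_node, bad] -
      (gam[bad] / N) * ch$J[bad] / grid$dtheta
  }

  Da3 <- theta_derivative(a3, grid)
  gDa3 <- sweep(Da3, 2, gam, `*`)
  # coupling through the two-point field: beta * int dgamma' F(pi,gamma') *
  # C33(pi, gamma'; theta, gamma), smooth part only (self-delta is analytic)
  pi_rows <- grid$firing_node + (seq_along(gam) - 1L) * grid$M
  coup <- beta * crossprod(S[pi_rows, , drop = FALSE], w * Fpi)
  kappadot <- trail_kappa_dot(ch, model, grid, convention, da1)
  dCreg <- -relax * Creg + matrix(coup, grid$M, length(gam)) - gDa3 * C11 +
    matrix(ch$s * ch$J / (2 * pi), grid$M, length(gam), byrow = TRUE) -
    outer(W, ch$resid) - outer(K, kappadot + relax * ch$kappa)

  dC11 <- -2 * relax * C11 + 2 * beta * sum(w * Fpi * Cpi)

  v <- as.vector(gDa3)
  Cf <- as.vector(Cfull)
  dS <- -(outer(v, Cf) + outer(Cf, v))
  list(da1 = da1, da3 = da3, dCreg = dCreg, dC11 = dC11, dS = dS)
}

# explicit midpoint (RK2) source sub-step over h
gae_source_step <- function(t, y, h, model, grid, fluct, convention) {
  d1 <- gae_source_derivs(t, y$a1, y$a3, y$Creg, y$C11, y$S, model, grid,
                          fluct, convention)
  d2 <- gae_source_derivs(t + h / 2,
                          y$a1 + h / 2 * d1$da1, y$a3 + h / 2 * d1$da3,
                          y$Creg + h / 2 * d1$dCreg,
                          y$C11 + h / 2 * d1$dC11,
                          y$S + h / 2 * d1$dS, model, grid, fluct, convention)
  list(a1 = y$a1 + h * d2$da1, a3 = y$a3 + h * d2$da3,
       Creg = y$Creg + h * d2$dCreg, C11 = y$C11 + h * d2$dC11,
       S = y$S + h * d2$dS)
}

# one Strang step: half sources, full semi-Lagrangian advection (rigid
# rotation by (I + gamma a1) h per gamma slice, cubic Lagrange, conservative),
# half sources. Subdivides when the shift exceeds max_shift_factor cells.
gae_strang_step <- function(t, y, h, model, grid, fluct, convention,
                            max_shift_factor = 4) {
  gam <- grid$gamma_nodes
  Iv <- drive_value(model$drive, t + h / 2)
  smax <- max(abs(Iv + gam * y$a1))
  nsub <- max(1L, ceiling(smax * h / (max_shift_factor * grid$dtheta)))
  hs <- h / nsub
  for (k in seq_len(nsub)) {
    y <- gae_source_step(t, y, hs / 2, model, grid, fluct, convention)
    speeds <- drive_value(model$drive, t + hs / 2) + gam * y$a1
    sh_list <- lapply(speeds * hs, shift_matrix, grid = grid)
    for (q in seq_along(gam)) {
      y$a3[, q] <- sh_list[[q]] %*% y$a3[, q]
      if (fluct) y$Creg[, q] <- sh_list[[q]] %*% y$Creg[, q]
    }
    if (fluct) {
      Sh <- block_diag(sh_list)
      y$S <- Sh %*% y$S %*% t(Sh)
    }
    y <- gae_source_step(t + hs / 2, y, hs / 2, model, grid, fluct,
                         convention)
    t <- t + hs
  }
  y
}

block_diag <- function(mats) {
  if (length(mats) == 1L) return(mats[[1]])
  M <- nrow(mats[[1]])
  out <- matrix(0, M * length(mats), M * length(mats))
  for (q in seq_along(mats)) {
    idx <- (q - 1L) * M + seq_len(M)
    out[idx, idx] <- mats[[q]]
  }
  out
}

#' Advance the generalized activity equations by one step
#'
#' One Strang-split step of the closed moment system for `linear_phase`
#' dynamics (the family F = I + gamma u for which the closure is derived):
#' half-step of the source/relaxation terms (explicit midpoint), a full
#' semi-Lagrangian advection of a3, C and both arguments of C33 by the
#' theta-independent speeds I + gamma a1 (rigid rotation, periodic cubic
#' Lagrange interpolation), and a second source half-step. The firing-line
#' delta source is carried by the firing node with mass 1/dtheta.
#'
#' @param state a `moment_state` from [init_moments()] or a previous step.
#' @param model the generating [model_spec()].
#' @param dt step length.
#' @param fluctuation_terms set `FALSE` to drop every 1/N coupling term, which
#'   reduces the system exactly to the mean-field equations on the same grid.
#' @param max_shift_factor advection sub-stepping guard: a step whose shift
#'   exceeds this many cells is subdivided.
#' @return the advanced `moment_state`.
#' @export
step_gae <- function(state, model, dt, fluctuation_terms = TRUE,
                     max_shift_factor = 4) {
  stopifnot(inherits(state, "moment_state"), inherits(model, "model_spec"))
  if (model$dynamics_kind != "linear_phase") {
    stop("the generalized activity equations are implemented for ",
         "linear_phase dynamics (F = I + gamma u)", call. = FALSE)
  }
  grid <- state$grid
  reg <- full_to_reg(state$t, state$a1, state$a3, state$C, model, grid,
                     state$convention)
  y <- list(a1 = state$a1, a3 = reg$a3, Creg = reg$Creg,
            C11 = state$C11, S = strip_self_delta(state))
  y <- gae_strang_step(state$t, y, dt, model, grid, fluctuation_terms,
                       state$convention, max_shift_factor)
  full <- reg_to_full(state$t + dt, y, model, grid, state$convention)
  new_moment_state(t = state$t + dt, a1 = y$a1, a3 = full$a3, C = full$C,
                   C11 = y$C11,
                   C33 = add_self_delta(y$S, full$a3, grid,
                                        state$convention),
                   N = state$N, convention = state$convention,
                   grid = grid)
}

#' Solve the order-1/N generalized activity equations
#'
#' Steps the closed system for (a1, a3, C, C11, C33) from the i.i.d. initial
#' state to time T, recording scalar series at every step and full
#' `moment_state` snapshots at requested times. State invariants (density
#' normalization, C33 swap symmetry, C11 nonnegativity) are checked at every
#' snapshot; violations beyond tolerance are collected in the returned
#' `run_log` with the offending time rather than stopping the run.
#'
#' @inheritParams step_gae
#' @param grid a [phase_grid()] matching the model's gamma law.
#' @param T duration.
#' @param dt step.
#' @param convention cumulant convention for C33, `"ordinary"` (default) or
#'   `"factorial"`; the ordinary convention reproduces raw Monte-Carlo
#'   density statistics (see the package vignette).
#' @param snapshot_times times at which full states are stored (default
#'   `c(0, T)`).
#' @return an object of class `gae_solution`: `times`, `a1_series`,
#'   `C11_series`, `C_pi_series` (steps x Q matrix of the firing-line value
#'   of C), `snapshots` (list of `moment_state`), `snapshot_times`,
#'   `convention`, `run_log`.
#' @examples
#' gl <- gamma_point(0)
#' m <- model_spec(N = 200, beta = 1, drive = 1, gamma_law = gl)
#' sol <- solve_gae(m, phase_grid(32, gl), T = 1, dt = 0.02)
#' sol$C11_series[length(sol$times)] # N Var(u) building up from zero
#' @export
solve_gae <- function(model, grid, T, dt,
                      convention = c("ordinary", "factorial"),
                      snapshot_times = NULL, fluctuation_terms = TRUE,
                      max_shift_factor = 4) {
  convention <- match.arg(convention)
  stopifnot(inherits(model, "model_spec"), inherits(grid, "phase_grid"))
  if (model$dynamics_kind != "linear_phase") {
    stop("the generalized activity equations are implemented for ",
         "linear_phase dynamics (F = I + gamma u)", call. = FALSE)
  }
  if (is.null(snapshot_times)) snapshot_times <- c(0, T)
  snapshot_times <- sort(snapshot_times)

  st <- init_moments(model, grid, convention)
  reg <- full_to_reg(0, st$a1, st$a3, st$C, model, grid, convention)
  y <- list(a1 = st$a1, a3 = reg$a3, Creg = reg$Creg,
            C11 = st$C11, S = strip_self_delta(st))
  nsteps <- ceiling(T / dt - 1e-9)
  times <- c(0, dt * seq_len(nsteps))
  times[length(times)] <- min(times[length(times)], T)
  Q <- length(grid$gamma_nodes)
  a1s <- C11s <- numeric(length(times))
  Cpis <- matrix(0, length(times), Q)
  a1s[1] <- y$a1
  run_log <- character(0)

  snaps <- vector("list", length(snapshot_times))
  si <- 1L
  make_state <- function(t, y) {
    full <- reg_to_full(t, y, model, grid, convention)
    new_moment_state(t = t, a1 = y$a1, a3 = full$a3, C = full$C,
                     C11 = y$C11,
                     C33 = add_self_delta(y$S, full$a3, grid, convention),
                     N = model$N, convention = convention, grid = grid)
  }
  take_snaps <- function(t, y) {
    while (si <= length(snapshot_times) &&
           snapshot_times[si] <= t + 1e-12) {
      s <- make_state(t, y)
      run_log <<- c(run_log, check_moment_invariants(s))
      snaps[[si]] <<- s
      si <<- si + 1L
    }
  }
  take_snaps(0, y)

  for (k in seq_len(nsteps)) {
    h <- times[k + 1] - times[k]
    y <- gae_strang_step(times[k], y, h, model, grid, fluctuation_terms,
                         convention, max_shift_factor)
    a1s[k + 1] <- y$a1
    C11s[k + 1] <- y$C11
    ch <- trail_channels(times[k + 1], y$a1, y$a3, model, grid, convention)
    Cpis[k + 1, ] <- y$Creg[grid$firing_node, ] + ch$kappa * pi / 4
    take_snaps(times[k + 1], y)
  }

  structure(list(times = times, a1_series = a1s, C11_series = C11s,
                 C_pi_series = Cpis,
                 snapshots = snaps[seq_len(si - 1L)],
                 snapshot_times = snapshot_times[seq_len(si - 1L)],
                 convention = convention, N = model$N,
                 fluctuation_terms = fluctuation_terms,
                 run_log = run_log),
            class = "gae_solution")
}

#' @export
print.gae_solution <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "<gae_solution> (%s cumulants%s) T = %g: a1 = %.6g, C11 = %.6g\n",
    x$convention,
    if (x$fluctuation_terms) "" else ", 1/N terms disabled",
    x$times[n], x$a1_series[n], x$C11_series[n]))
  if (length(x$run_log)) {
    cat("  run log:\n")
    cat(paste0("   - ", x$run_log, collapse = "\n"), "\n")
  }
  invisible(x)
}

# invariant checks used by solve_gae's run log
check_moment_invariants <- function(state, norm_tol = 1e-6,
                                    sym_tol = 1e-10, c11_tol = 1e-8) {
  msgs <- character(0)
  total <- grid_integral(state$a3, state$grid)
  if (abs(total - 1) > norm_tol) {
    msgs <- c(msgs, sprintf("t = %g: integral a3 = %.10g departs from 1",
                            state$t, total))
  }
  asym <- max(abs(state$C33 - t(state$C33)))
  if (asym > sym_tol) {
    msgs <- c(msgs, sprintf("t = %g: C33 swap asymmetry %.3g", state$t, asym))
  }
  if (state$C11 < -c11_tol) {
    msgs <- c(msgs, sprintf("t = %g: C11 = %.3g < 0", state$t, state$C11))
  }
  msgs
}
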