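#' Empirical phase density on a grid
#'
#' Histogram estimator of the neuron density eta(theta, gamma): phases are
#' wrapped into \[-pi, pi) and assigned to node-centered bins (the bin of
#' node m covers theta_m +/- dtheta/2, so the firing-phase bin at node 1
#' straddles the identified boundary), gammas to their nearest quadrature
#' node. Bin values are count/(N dtheta w_q), so the grid integral is exactly
#' 1.
#'
#' @param phases N phase angles.
#' @param gammas N coupling values.
#' @param grid a [phase_grid()].
#' @return M x Q density matrix.
#' @examples
#' g <- phase_grid(4, gamma_point(0))
#' estimate_density(c(-pi, -pi / 2, 0, pi / 2), rep(0, 4), g) # all 1/(2*pi)
#' @export
estimate_density <- function(phases, gammas, grid) {
  stopifnot(inherits(grid, "phase_grid"), length(phases) == length(gammas))
  .phase_histogram(as.numeric(phases), as.numeric(gammas),
                   grid$gamma_nodes, grid$gamma_weights, grid$M)
}

#' Run a seeded ensemble of microscopic simulations
#'
#' Repeats the microscopic simulation over R independent initial conditions
#' (realization r uses seed `base_seed + r`) and estimates the moment
#' quantities that the mean-field and activity-equation solvers predict:
#' the ensemble mean drive, the N-scaled drive variance
#' `C11_hat = N Var(u(t))`, the mean empirical density, the N-scaled
#' drive-density cross covariance `C13_hat = N Cov(u, eta(theta, gamma))`,
#' and optionally the two-point density covariance C33_hat. All standard
#' errors are moment-based (sd of the per-realization contribution / sqrt R).
#'
#' @param model a [model_spec()].
#' @param R number of realizations (>= 2).
#' @param base_seed integer; realization r uses seed base_seed + r.
#' @param grid a [phase_grid()] for density estimates.
#' @param sample_times output times.
#' @param mode simulation mode, see [simulate_network()].
#' @param dt fixed-step step size (fixed_step mode only).
#' @param estimate character subset of `c("u", "density", "C13", "C33")`;
#'   density-based estimators store an R x M x Q slab per sample time, so
#'   restrict `sample_times` when requesting them. `"C33"` additionally
#'   requires a coarse grid (M <= 64).
#' @param return_raw keep the R x S matrix of per-realization drive values
#'   (for split-half diagnostics).
#' @return an object of class `ensemble_stats`.
#' @export
run_ensemble <- function(model, R, base_seed, grid, sample_times,
                         mode = c("event_driven", "fixed_step"), dt = 1e-3,
                         estimate = c("u", "density", "C13"),
                         return_raw = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "model_spec"), inherits(grid, "phase_grid"))
  if (R < 2) stop("R >= 2 realizations are needed to form variances",
                  call. = FALSE)
  estimate <- match.arg(estimate, c("u", "density", "C13", "C33"),
                        several.ok = TRUE)
  need_density <- any(c("density", "C13", "C33") %in% estimate)
  if ("C33" %in% estimate && grid$M > 64) {
    stop("C33_hat estimation is restricted to coarse grids (M <= 64)",
         call. = FALSE)
  }
  sample_times <- sort(as.numeric(sample_times))
  S <- length(sample_times)
  M <- grid$M
  Q <- length(grid$gamma_nodes)
  N <- model$N
  Tend <- max(sample_times)

  u_mat <- matrix(NA_real_, R, S)
  dens <- if (need_density) array(0, c(R, M * Q, S)) else NULL

  for (r in seq_len(R)) {
    init <- draw_initial_state(model, base_seed + r)
    tr <- simulate_network(model, seed = base_seed + r, T = Tend, mode = mode,
                           sample_times = sample_times, dt = dt,
                           record_spikes = FALSE,
                           record_phases = need_density, init = init)
    u_mat[r, ] <- tr$u_series
    if (need_density) {
      for (s in seq_len(S)) {
        dens[r, , s] <- .phase_histogram(tr$phase_snapshots[s, ],
                                         init$gammas, grid$gamma_nodes,
                                         grid$gamma_weights, M)
      }
    }
  }

  mean_u <- colMeans(u_mat)
  se_mean_u <- apply(u_mat, 2, stats::sd) / sqrt(R)
  dev_u <- sweep(u_mat, 2, mean_u)
  C11_hat <- N * colSums(dev_u^2) / (R - 1)
  se_C11 <- N * apply(dev_u^2, 2, stats::sd) / sqrt(R)

  density_mean <- C13_hat <- se_C13 <- NULL
  C33_hat <- NULL
  if (need_density) {
    density_mean <- array(apply(dens, c(2, 3), mean), c(M, Q, S))
    if ("C13" %in% estimate) {
      C13_hat <- array(0, c(M, Q, S))
      se_C13 <- array(0, c(M, Q, S))
      for (s in seq_len(S)) {
        dd <- sweep(dens[, , s, drop = TRUE], 2, colMeans(dens[, , s]))
        z <- dd * dev_u[, s]                 # per-realization product
        C13_hat[, , s] <- N * colSums(z) / (R - 1)
        se_C13[, , s] <- N * apply(z, 2, stats::sd) / sqrt(R)
      }
    }
    if ("C33" %in% estimate) {
      C33_hat <- array(0, c(M * Q, M * Q, S))
      for (s in seq_len(S)) {
        C33_hat[, , s] <- N * stats::cov(dens[, , s])
      }
    }
  }

  structure(list(sample_times = sample_times, mean_u = mean_u,
                 se_mean_u = se_mean_u, C11_hat = C11_hat, se_C11 = se_C11,
                 density = density_mean, C13_hat = C13_hat,
                 se_C13 = se_C13, C33_hat = C33_hat,
                 R = R, N = N, base_seed = base_seed, grid = grid,
                 u_mat = if (return_raw) u_mat else NULL),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  S <- length(x$sample_times)
  cat(sprintf(
    "<ensemble_stats> R = %d realizations of N = %d over %d sample time(s)\n",
    x$R, x$N, S))
  cat(sprintf("  mean_u(T) = %.6g (se %.2g), C11_hat(T) = %.6g (se %.2g)\n",
              x$mean_u[S], x$se_mean_u[S], x$C11_hat[S], x$se_C11[S]))
  invisible(x)
}

#' Finite-size convergence check against a mean-field reference
#'
#' Compares ensembles at N and 2N to a mean-field a1(t) reference: reports
#' the sup-norm errors e_N = max_t |mean_u - a1| and their ratio. At first
#' order in the system-size expansion the deviation of the ensemble mean from
#' mean field is proportional to 1/N, so the ratio should approach 2 wherever
#' the errors stand clear of Monte-Carlo noise (`resolved` reports whether
#' SE < e_N / 5 at the attaining time).
#'
#' @param stats_N,stats_2N `ensemble_stats` at N and 2N (same sample times).
#' @param reference mean-field a1 values at the same sample times (or a
#'   `mean_field_solution` whose times contain them).
#' @return list with `e_N`, `e_2N`, `ratio`, `resolved`, and per-time errors.
#' @export
scaling_check <- function(stats_N, stats_2N, reference) {
  stopifnot(inherits(stats_N, "ensemble_stats"),
            inherits(stats_2N, "ensemble_stats"))
  if (length(stats_N$sample_times) != length(stats_2N$sample_times) ||
      any(abs(stats_N$sample_times - stats_2N$sample_times) > 1e-9)) {
    stop("ensembles must share identical sample times", call. = FALSE)
  }
  a1 <- if (inherits(reference, "mean_field_solution")) {
    stats::approx(reference$times, reference$a1_series,
                  xout = stats_N$sample_times)$y
  } else {
    as.numeric(reference)
  }
  if (length(a1) != length(stats_N$sample_times)) {
    stop("reference length does not match the sample times", call. = FALSE)
  }
  err_N <- abs(stats_N$mean_u - a1)
  err_2N <- abs(stats_2N$mean_u - a1)
  iN <- which.max(err_N)
  i2N <- which.max(err_2N)
  e_N <- err_N[iN]
  e_2N <- err_2N[i2N]
  list(e_N = e_N, e_2N = e_2N, ratio = e_N / e_2N,
       resolved = stats_N$se_mean_u[iN] < e_N / 5 &&
                  stats_2N$se_mean_u[i2N] < e_2N / 5,
       err_N = err_N, err_2N = err_2N,
       se_N = stats_N$se_mean_u, se_2N = stats_2N$se_mean_u)
}

#' Compare an activity-equation solution with ensemble estimates
#'
#' Emits per-quantity z-scores (prediction minus estimate, over the
#' estimate's standard error) for C11(t) and the firing-line cross covariance
#' C(pi, gamma, t) at the ensemble's sample times.
#'
#' @param gae a `gae_solution`.
#' @param stats an `ensemble_stats` with C13 estimates.
#' @return data.frame with columns quantity, time, gamma, predicted,
#'   estimated, se, z.
#' @export
compare_moments <- function(gae, stats) {
  stopifnot(inherits(gae, "gae_solution"), inherits(stats, "ensemble_stats"))
  grid <- stats$grid
  out <- list()
  for (s in seq_along(stats$sample_times)) {
    ts <- stats$sample_times[s]
    k <- which.min(abs(gae$times - ts))
    out[[length(out) + 1L]] <- data.frame(
      quantity = "C11", time = ts, gamma = NA_real_,
      predicted = gae$C11_series[k], estimated = stats$C11_hat[s],
      se = stats$se_C11[s],
      z = (gae$C11_series[k] - stats$C11_hat[s]) / stats$se_C11[s])
    if (!is.null(stats$C13_hat)) {
      for (q in seq_along(grid$gamma_nodes)) {
        pred <- gae$C_pi_series[k, q]
        est <- stats$C13_hat[grid$firing_node, q, s]
        se <- stats$se_C13[grid$firing_node, q, s]
        out[[length(out) + 1L]] <- data.frame(
          quantity = "C_pi", time = ts, gamma = grid$gamma_nodes[q],
          predicted = pred, estimated = est, se = se, z = (pred - est) / se)
      }
    }
  }
  do.call(rbind, out)
}
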