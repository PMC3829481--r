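#' Periodic phase grid with gamma quadrature
#'
#' Discretization support for fields on the periodic phase domain
#' \[-pi, pi) crossed with the gamma quadrature. The theta nodes are uniform,
#' theta_m = -pi + (m-1)*dtheta with dtheta = 2*pi/M; node 1 sits at the
#' identified boundary theta = pi == -pi, the firing phase, so the firing-line
#' delta source lives on a single well-defined node. Fields on the grid are
#' M x Q matrices (Q = number of gamma nodes) with integration measure
#' dtheta * w_q.
#'
#' @param M number of theta nodes.
#' @param gamma_law a [gamma_point()]-style law supplying the gamma nodes and
#'   weights (weights must sum to 1 within 1e-12).
#' @return an object of class `phase_grid` with elements `M`, `dtheta`,
#'   `theta_nodes`, `gamma_nodes`, `gamma_weights`, and `firing_node` (= 1).
#' @examples
#' g <- phase_grid(8, gamma_point(0.5))
#' g$theta_nodes
#' @export
phase_grid <- function(M, gamma_law = gamma_point(0)) {
  M <- as.integer(M)
  stopifnot(!is.na(M), M >= 4L, inherits(gamma_law, "gamma_law"))
  dtheta <- 2 * pi / M
  structure(list(
    M = M,
    dtheta = dtheta,
    theta_nodes = -pi + (seq_len(M) - 1L) * dtheta,
    gamma_nodes = gamma_law$nodes,
    gamma_weights = gamma_law$weights,
    firing_node = 1L
  ), class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("<phase_grid> M = %d (dtheta = %.4g), %d gamma node(s)\n",
              x$M, x$dtheta, length(x$gamma_nodes)))
  invisible(x)
}

#' Integrate a field over the grid
#'
#' Computes the double integral over theta and gamma of a field given as an
#' M x Q matrix (or length-M vector for a single gamma node), using the
#' rectangle rule in theta (exact for trigonometric polynomials up to the
#' grid's Nyquist order) and the gamma quadrature weights.
#'
#' @param field M x Q matrix of field values.
#' @param grid a `phase_grid`.
#' @return scalar integral.
#' @export
grid_integral <- function(field, grid) {
  field <- as.matrix(field)
  stopifnot(nrow(field) == grid$M, ncol(field) == length(grid$gamma_nodes))
  grid$dtheta * sum(colSums(field) * grid$gamma_weights)
}

#' Population firing rate from the density at the firing phase
#'
#' The population rate is the flux of neurons through the firing phase:
#' nu = integral over gamma of F(pi, gamma, u) * density(pi, gamma), a
#' weighted sum over the gamma quadrature. For the theta-neuron family the
#' speed at the firing phase is drive-independent (F(pi, .) = 2).
#'
#' @param density_at_pi per-gamma density values at the node identified with
#'   theta = pi (length Q).
#' @param u shared drive value.
#' @param I external drive value.
#' @param gamma_law a `gamma_law` (nodes/weights of length Q).
#' @param kind dynamics kind, `"linear_phase"` (default) or `"theta"`.
#' @return scalar population rate nu.
#' @examples
#' # uniform density, gamma point mass at 0, I = 1: nu = 1/(2*pi)
#' firing_rate(1 / (2 * pi), u = 3, I = 1, gamma_law = gamma_point(0))
#' @export
firing_rate <- function(density_at_pi, u, I, gamma_law,
                        kind = c("linear_phase", "theta")) {
  kind <- match.arg(kind)
  stopifnot(inherits(gamma_law, "gamma_law"))
  q <- length(gamma_law$nodes)
  if (length(density_at_pi) != q) {
    stop(sprintf(
      "firing_rate: density_at_pi has length %d but gamma_law has %d node(s)",
      length(density_at_pi), q), call. = FALSE)
  }
  speeds <- velocity(pi, gamma_law$nodes, u, I, kind)
  sum(gamma_law$weights * speeds * density_at_pi)
}

#' Sample an initial phase density on a grid
#'
#' Point-samples rho0 at the theta nodes for every gamma node and rescales so
#' the grid integral is exactly 1 (the rescaling is a relative change at the
#' quadrature-error level for smooth densities).
#'
#' @param rho0 a `rho0_law`.
#' @param grid a `phase_grid`.
#' @return M x Q density matrix.
#' @export
rho0_on_grid <- function(rho0, grid) {
  v <- rho0_density(rho0, grid$theta_nodes)
  field <- matrix(v, nrow = grid$M, ncol = length(grid$gamma_nodes))
  field / grid_integral(field, grid)
}

# --- internal grid numerics -------------------------------------------------

# periodic central difference d/dtheta, column-wise on an M x Q matrix
theta_derivative <- function(field, grid) {
  field <- as.matrix(field)
  M <- grid$M
  up <- field[c(2:M, 1L), , drop = FALSE]
  dn <- field[c(M, 1:(M - 1L)), , drop = FALSE]
  (up - dn) / (2 * grid$dtheta)
}

# circulant matrix performing a rigid periodic shift of a length-M field by
# `shift` radians (semi-Lagrangian: value at node m is taken from m - shift)
# with 4-point (cubic Lagrange) interpolation; columns sum to 1, so the
# rectangle-rule integral of any shifted field is conserved exactly.
shift_matrix <- function(shift, grid) {
  M <- grid$M
  s <- shift / grid$dtheta           # shift in node units
  k <- floor(s)
  f <- s - k                         # fractional part in [0, 1)
  # Lagrange weights on stencil offsets (-1, 0, 1, 2) around the integer part
  w <- c(-f * (f - 1) * (f - 2) / 6,
         (f + 1) * (f - 1) * (f - 2) / 2,
         -(f + 1) * f * (f - 2) / 2,
         (f + 1) * f * (f - 1) / 6)
  A <- matrix(0, M, M)
  idx <- seq_len(M)
  for (j in 1:4) {
    src <- ((idx - 1L - k - (j - 2L)) %% M) + 1L
    A[cbind(idx, src)] <- A[cbind(idx, src)] + w[j]
  }
  A
}
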