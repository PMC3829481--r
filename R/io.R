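#' Run configurations
#'
#' A `run_config` bundles a [model_spec()], the grid settings and the solver
#' settings into one serializable object. [write_run_config()] emits a flat
#' YAML file (tabulated initial densities and drive time series go to
#' two-column CSV side files next to it) and [read_run_config()] restores it;
#' the parse -> emit -> parse round trip is the identity.
#'
#' @param model a [model_spec()].
#' @param grid_M number of theta nodes for grid-based solvers.
#' @param solver named list of solver settings (T, dt, mode, convention, R,
#'   base_seed, ...).
#' @param output output directory for CLI runs.
#' @param log_level one of "quiet", "info", "debug".
#' @return an object of class `run_config`.
#' @export
run_config <- function(model, grid_M = 64, solver = list(), output = ".",
                       log_level = "info") {
  stopifnot(inherits(model, "model_spec"))
  structure(list(model = model, grid_M = as.integer(grid_M),
                 solver = solver, output = output, log_level = log_level),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$model)
  cat(sprintf("  grid M = %d; solver: %s\n", x$grid_M,
              paste(names(x$solver), unlist(x$solver), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Canonical study configurations
#'
#' Ready-made scenarios: `uniform_pointmass` is the asynchronous regime
#' (uniform initial phases, single coupling value) in which the mean field
#' collapses to the Wilson-Cowan rate equation; `bump_pointmass` starts from
#' a wrapped-bump density, where the full phase conservation equation is
#' required; `uniform_mixture` draws the coupling from a two-component
#' mixture. `overrides` is a named list patched over the defaults
#' (recognized names: N, beta, I, gbar, u0, kappa, center, nodes, weights,
#' plus any `run_config` field).
#'
#' @param name fixture name.
#' @param overrides named list of overrides.
#' @return a valid `run_config`.
#' @examples
#' cfg <- make_fixture("uniform_pointmass", list(gbar = 1))
#' cfg$model$gamma_law$nodes
#' @export
make_fixture <- function(name = c("uniform_pointmass", "bump_pointmass",
                                  "uniform_mixture"),
                         overrides = list()) {
  name <- match.arg(name)
  p <- list(N = 200L, beta = 1, I = 1, gbar = 0.5, u0 = 0,
            kappa = 2, center = 0, nodes = c(0.25, 0.75),
            weights = c(0.5, 0.5),
            grid_M = 64, solver = list(T = 10, dt = 5e-3,
                                       mode = "event_driven",
                                       convention = "ordinary",
                                       R = 1000, base_seed = 1),
            output = ".", log_level = "info")
  known <- names(p)
  bad <- setdiff(names(overrides), known)
  if (length(bad)) {
    stop("unknown fixture override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  p <- utils::modifyList(p, overrides)
  gl <- switch(name,
    uniform_pointmass = gamma_point(p$gbar),
    bump_pointmass = gamma_point(p$gbar),
    uniform_mixture = gamma_mixture(p$nodes, p$weights))
  rho <- if (name == "bump_pointmass") {
    rho_bump(p$center, p$kappa)
  } else {
    rho_uniform()
  }
  model <- model_spec(N = p$N, beta = p$beta, drive = p$I, gamma_law = gl,
                      u0 = p$u0, rho0 = rho)
  run_config(model, grid_M = p$grid_M, solver = p$solver,
             output = p$output, log_level = p$log_level)
}

# ---- YAML config serialization --------------------------------------------

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path; tabulated series go to `<path>-rho0.csv` /
#'   `<path>-drive.csv`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  m <- config$model
  lst <- list(
    model = list(N = m$N, beta = m$beta, dynamics_kind = m$dynamics_kind,
                 u0 = m$u0,
                 drive = if (m$drive$kind == "constant") {
                   list(kind = "constant", value = m$drive$value)
                 } else {
                   list(kind = "tabulated", file = paste0(basename(path),
                                                          "-drive.csv"))
                 },
                 gamma_law = list(kind = m$gamma_law$kind,
                                  nodes = as.list(m$gamma_law$nodes),
                                  weights = as.list(m$gamma_law$weights)),
                 rho0 = switch(m$rho0$kind,
                   uniform = list(kind = "uniform"),
                   bump = list(kind = "bump", center = m$rho0$center,
                               concentration = m$rho0$concentration),
                   tabulated = list(kind = "tabulated",
                                    file = paste0(basename(path),
                                                  "-rho0.csv")))),
    grid_M = config$grid_M,
    solver = config$solver,
    output = config$output,
    log_level = config$log_level)
  if (m$drive$kind == "tabulated") {
    write_two_column(paste0(path, "-drive.csv"), "time", m$drive$time,
                     "value", m$drive$values)
  }
  if (m$rho0$kind == "tabulated") {
    write_two_column(paste0(path, "-rho0.csv"), "theta", m$rho0$theta,
                     "value", m$rho0$values)
  }
  yaml::write_yaml(lst, path, precision = 17)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  ml <- lst$model
  drive <- if (ml$drive$kind == "constant") {
    drive_constant(ml$drive$value)
  } else {
    tab <- utils::read.csv(file.path(dirname(path), ml$drive$file))
    drive_tabulated(tab[[1]], tab[[2]])
  }
  gl <- new_gamma_law(unlist(ml$gamma_law$nodes),
                      unlist(ml$gamma_law$weights), ml$gamma_law$kind)
  rho <- switch(ml$rho0$kind,
    uniform = rho_uniform(),
    bump = rho_bump(ml$rho0$center, ml$rho0$concentration),
    tabulated = {
      tab <- utils::read.csv(file.path(dirname(path), ml$rho0$file))
      rho_tabulated(tab[[1]], tab[[2]])
    })
  model <- model_spec(N = ml$N, beta = ml$beta, drive = drive,
                      gamma_law = gl, dynamics_kind = ml$dynamics_kind,
                      u0 = ml$u0, rho0 = rho)
  run_config(model, grid_M = lst$grid_M, solver = lst$solver,
             output = lst$output, log_level = lst$log_level)
}

write_two_column <- function(path, n1, v1, n2, v2) {
  df <- data.frame(a = sprintf("%.17g", v1), b = sprintf("%.17g", v2))
  names(df) <- c(n1, n2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# ---- field container -------------------------------------------------------

#' Lossless field container
#'
#' Persists named numeric fields (scalars, vectors, matrices, arrays) to a
#' directory container: one full-precision CSV per field plus a JSON metadata
#' file carrying the dimensions, the declared grid/seed metadata and a
#' content hash of the field names. The write -> read round trip is bitwise
#' exact (values are written with 17 significant digits). Reading with
#' mismatched metadata (e.g. a different grid) raises a format error.
#'
#' @param path container directory (created if needed).
#' @param fields named list of numeric objects.
#' @param metadata named list of scalar metadata (grid size, seeds, ...).
#' @param expect_metadata on read: named list that must match the stored
#'   metadata exactly.
#' @return `write_fields` returns `path`; `read_fields` returns a list with
#'   `fields` and `metadata`.
#' @export
write_fields <- function(path, fields, metadata = list()) {
  stopifnot(is.list(fields), length(names(fields)) == length(fields))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(container = "spikemoments-fields", version = 1L,
               fields = lapply(fields, function(f) {
                 list(dim = if (is.null(dim(f))) length(f) else dim(f))
               }),
               metadata = metadata)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(fields)) {
    v <- as.numeric(fields[[nm]])
    writeLines(sprintf("%.17g", v), file.path(path, paste0(nm, ".csv")))
  }
  invisible(path)
}

#' @rdname write_fields
#' @export
read_fields <- function(path, expect_metadata = NULL) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    stop("not a field container (missing meta.json): ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyMatrix = FALSE)
  if (!identical(meta$container, "spikemoments-fields")) {
    stop("unrecognized container format in ", path, call. = FALSE)
  }
  if (!is.null(expect_metadata)) {
    for (nm in names(expect_metadata)) {
      stored <- meta$metadata[[nm]]
      if (is.null(stored) ||
          !isTRUE(all.equal(unname(unlist(stored)),
                            unname(unlist(expect_metadata[[nm]]))))) {
        stop(sprintf(
          "field container metadata mismatch for '%s': stored %s, expected %s",
          nm, paste(unlist(stored), collapse = ","),
          paste(unlist(expect_metadata[[nm]]), collapse = ",")),
          call. = FALSE)
      }
    }
  }
  fields <- list()
  for (nm in names(meta$fields)) {
    v <- as.numeric(readLines(file.path(path, paste0(nm, ".csv"))))
    d <- unlist(meta$fields[[nm]]$dim)
    if (length(v) != prod(d)) {
      stop(sprintf("field '%s' has %d values but dim %s", nm, length(v),
                   paste(d, collapse = "x")), call. = FALSE)
    }
    fields[[nm]] <- if (length(d) > 1L) array(v, dim = d) else v
  }
  list(fields = fields, metadata = meta$metadata)
}

#' Persist a moment state or ensemble statistics
#'
#' Thin wrappers storing the standard field layout (/a1, /a3, /C, /C11,
#' /C33 for moment states; /mean_u, /C11, /C13, /density with /se companions
#' for ensembles) in a [write_fields()] container.
#'
#' @param state a `moment_state`.
#' @param stats an `ensemble_stats`.
#' @param path container directory.
#' @export
write_moment_state <- function(state, path) {
  stopifnot(inherits(state, "moment_state"))
  write_fields(path,
    fields = list(a1 = state$a1, a3 = state$a3, C = state$C,
                  C11 = state$C11, C33 = state$C33, time = state$t),
    metadata = list(M = state$grid$M,
                    gamma_nodes = state$grid$gamma_nodes,
                    gamma_weights = state$grid$gamma_weights,
                    N = state$N, convention = state$convention))
}

#' @rdname write_moment_state
#' @export
read_moment_state <- function(path, grid = NULL) {
  got <- read_fields(path, expect_metadata = if (!is.null(grid)) {
    list(M = grid$M, gamma_nodes = grid$gamma_nodes,
         gamma_weights = grid$gamma_weights)
  })
  md <- got$metadata
  if (is.null(grid)) {
    law <- new_gamma_law(unlist(md$gamma_nodes), unlist(md$gamma_weights),
                         "quadrature")
    grid <- phase_grid(md$M, law)
  }
  f <- got$fields
  new_moment_state(t = f$time, a1 = f$a1, a3 = f$a3, C = f$C, C11 = f$C11,
                   C33 = f$C33, N = md$N, convention = md$convention,
                   grid = grid)
}

#' @rdname write_moment_state
#' @export
write_ensemble_stats <- function(stats, path) {
  stopifnot(inherits(stats, "ensemble_stats"))
  fields <- list(time = stats$sample_times, mean_u = stats$mean_u,
                 mean_u_se = stats$se_mean_u, C11 = stats$C11_hat,
                 C11_se = stats$se_C11)
  if (!is.null(stats$density)) fields$density <- stats$density
  if (!is.null(stats$C13_hat)) {
    fields$C13 <- stats$C13_hat
    fields$C13_se <- stats$se_C13
  }
  if (!is.null(stats$C33_hat)) fields$C33 <- stats$C33_hat
  write_fields(path, fields,
               metadata = list(M = stats$grid$M,
                               gamma_nodes = stats$grid$gamma_nodes,
                               gamma_weights = stats$grid$gamma_weights,
                               N = stats$N, R = stats$R,
                               base_seed = stats$base_seed))
}
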