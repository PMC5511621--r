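# Scenario orchestration: the main simulate_graft() driver, tracer-polygon
# area tracking, parameter sweeps, and output writers.

# barycentric interpolation weights of points in the reference triangulation
locate_points <- function(mesh, pts) {
  tri <- mesh$tri
  geo <- element_geometry(mesh$ref, tri)
  n_pts <- nrow(pts)
  el <- integer(n_pts); w <- matrix(0, n_pts, 3)
  for (p in seq_len(n_pts)) {
    found <- FALSE
    for (t in seq_len(nrow(tri))) {
      a <- mesh$ref[tri[t, 1], ]; b <- mesh$ref[tri[t, 2], ]
      cc <- mesh$ref[tri[t, 3], ]
      det <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
      l2 <- ((pts[p, 1] - a[1]) * (cc[2] - a[2]) -
               (cc[1] - a[1]) * (pts[p, 2] - a[2])) / det
      l3 <- ((b[1] - a[1]) * (pts[p, 2] - a[2]) -
               (pts[p, 1] - a[1]) * (b[2] - a[2])) / det
      l1 <- 1 - l2 - l3
      if (l1 >= -1e-10 && l2 >= -1e-10 && l3 >= -1e-10) {
        el[p] <- t; w[p, ] <- c(l1, l2, l3); found <- TRUE; break
      }
    }
    if (!found) stop("tracer point outside the mesh: (",
                     pts[p, 1], ", ", pts[p, 2], ")")
  }
  list(el = el, w = w)
}

# displaced tracer polygon area (absolute)
tracer_polygon_area <- function(tracers, mesh, state) {
  loc <- locate_points(mesh, tracers$ref)
  tri <- mesh$tri
  disp <- matrix(0, nrow(tracers$ref), 2)
  for (p in seq_len(nrow(tracers$ref))) {
    nd <- tri[loc$el[p], ]
    disp[p, ] <- loc$w[p, ] %*% state$u[nd, , drop = FALSE]
  }
  abs(polygon_area(tracers$ref + disp))
}

#' Relative surface area of the graft
#'
#' Shoelace area of the displaced tracer polygon divided by its reference
#' area: the readout that tracks graft contraction over time.
#'
#' @param tracers a \code{tracer_set}.
#' @param mesh a \code{graft_mesh} (reference coordinates are used to locate
#'   the material points).
#' @param state a \code{state_fields} carrying the displacement field.
#' @return dimensionless area ratio (1 at zero displacement).
#' @export
relative_area <- function(tracers, mesh, state) {
  tracer_polygon_area(tracers, mesh, state) / abs(polygon_area(tracers$ref))
}

#' Simulate graft contraction on the tissue slice
#'
#' Full pipeline: build the mesh and initial fields for the configured graft,
#' advance the coupled mechano-chemical system to \code{t_end} with the
#' positivity-preserving moving-grid engine, and track the relative surface
#' area of the graft through the tracer polygon.  Deterministic given a
#' configuration.
#'
#' @param params a completed \code{model_parameters} object.
#' @param t_end end time, days (default 365).
#' @param target_edge mesh spacing, cm (default 1).
#' @param epochs snapshot times, days; default is the display schedule
#'   \code{c(7, 14, 29, 56, 180, 365)} scaled by \code{t_end / 365}.
#' @param tracers_per_side tracer points per graft side (default 2: corners
#'   plus midpoints).
#' @param unwounded logical; TRUE replaces the graft by intact dermis
#'   (\code{w == 1}, no initial signal) for equilibrium-control runs.
#' @param ... engine settings forwarded to \code{\link{fem_run}} (\code{tol},
#'   \code{dt0}, \code{dt_max}, \code{quasi_static}, \code{refine_every},
#'   \code{checkpoint_path}, ...).
#' @return An object of class \code{graft_sim}: the \code{\link{fem_run}}
#'   result plus \code{params}, \code{tracers} and the settings used.
#' @export
#' @examples
#' \donttest{
#' p <- default_parameters()
#' sim <- simulate_graft(p, t_end = 40, target_edge = 2.5, tol = 5e-3)
#' summary(sim)
#' }
simulate_graft <- function(params, t_end = 365, target_edge = 1,
                           epochs = NULL, tracers_per_side = 2,
                           unwounded = FALSE, ...) {
  validate_parameters(params)
  if (!(t_end > 0)) stop("t_end must be > 0")
  if (is.null(epochs)) {
    epochs <- unique(pmin(round(c(7, 14, 29, 56, 180, 365) * t_end / 365, 2),
                          t_end))
  }
  mesh <- build_mesh(half_width = 10, target_edge = target_edge)
  if (unwounded) {
    params$c_w <- 0
    params$I_w <- 1
  }
  state <- initial_state(mesh, params)
  tracers <- place_tracers(params, n_per_side = tracers_per_side)
  run <- fem_run(mesh, state, params, t_end = t_end, epochs = epochs,
                 tracers = tracers, ...)
  run$params <- params
  run$tracers <- tracers
  run$settings <- list(t_end = t_end, target_edge = target_edge,
                       unwounded = unwounded)
  class(run) <- "graft_sim"
  run
}

#' Run a scenario from a configuration list
#'
#' Thin wrapper over \code{\link{simulate_graft}} taking a single
#' configuration list, convenient for sweeps and for the command-line
#' interface.
#'
#' @param config list with optional elements \code{params} (a
#'   \code{model_parameters}; default \code{default_parameters()}),
#'   \code{overrides} (named numeric parameter overrides, e.g.
#'   \code{list(zeta = 0)}), and any argument of \code{simulate_graft}.
#' @return a \code{graft_sim} object.
#' @export
run_scenario <- function(config = list()) {
  params <- config$params
  if (is.null(params)) params <- default_parameters()
  if (!is.null(config$overrides)) {
    for (k in names(config$overrides)) params[[k]] <- config$overrides[[k]]
    validate_parameters(params)
  }
  config$params <- NULL; config$overrides <- NULL
  do.call(simulate_graft, c(list(params = params), config))
}

#' Sweep the morphoelastic-rate and MMP-inhibition parameters
#'
#' Runs one scenario per (zeta, a_c_III) combination with identical numerical
#' settings and tabulates the contracture readouts.
#'
#' @param zeta numeric vector of morphoelastic-change rates,
#'   cm^6/(cells g day).
#' @param a_c_III numeric vector of MMP-secretion inhibition coefficients,
#'   cm^3/g.
#' @param params base parameter set (default \code{default_parameters()}).
#' @param ... scenario settings shared by all runs (t_end, target_edge, ...).
#' @return data.frame with columns \code{zeta}, \code{a_c_III},
#'   \code{final_relative_area}, \code{min_relative_area},
#'   \code{t_min_area}.
#' @export
sweep_scenarios <- function(zeta, a_c_III, params = default_parameters(),
                            ...) {
  grid <- expand.grid(zeta = zeta, a_c_III = a_c_III)
  if (nrow(grid) < 2) stop("a sweep needs at least 2 configurations")
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    sim <- run_scenario(c(list(overrides = list(zeta = grid$zeta[k],
                                                a_c_III = grid$a_c_III[k]),
                               params = params), list(...)))
    data.frame(zeta = grid$zeta[k], a_c_III = grid$a_c_III[k],
               final_relative_area = sim$relative_area[length(sim$relative_area)],
               min_relative_area = min(sim$relative_area),
               t_min_area = sim$times[which.min(sim$relative_area)])
  })
  do.call(rbind, rows)
}

#' @export
print.graft_sim <- function(x, ...) {
  cat("Morphoelastic graft contraction simulation\n")
  cat(sprintf("  mesh: %d nodes, %d triangles (edge %.3g cm)\n",
              nrow(x$mesh$ref), nrow(x$mesh$tri), x$settings$target_edge))
  cat(sprintf("  horizon: %.4g days, %d accepted steps\n",
              x$settings$t_end, length(x$times) - 1L))
  if (!all(is.na(x$relative_area))) {
    cat(sprintf("  relative area: min %.4f (day %.3g), final %.4f\n",
                min(x$relative_area),
                x$times[which.min(x$relative_area)],
                x$relative_area[length(x$relative_area)]))
  }
  invisible(x)
}

#' @export
summary.graft_sim <- function(object, ...) {
  x <- object
  out <- list(
    n_nodes = nrow(x$mesh$ref),
    n_steps = length(x$times) - 1L,
    t_end = x$settings$t_end,
    final_relative_area = x$relative_area[length(x$relative_area)],
    min_relative_area = min(x$relative_area),
    t_min_area = x$times[which.min(x$relative_area)],
    min_constituent = min(unlist(x$mins)),
    final_max_strain_norm = x$strain_norm[length(x$strain_norm)]
  )
  class(out) <- "summary.graft_sim"
  out
}

#' @export
print.summary.graft_sim <- function(x, ...) {
  cat("Graft contraction summary\n")
  cat(sprintf("  nodes %d, accepted steps %d, horizon %.4g days\n",
              x$n_nodes, x$n_steps, x$t_end))
  cat(sprintf("  relative area: min %.4f at day %.3g, final %.4f\n",
              x$min_relative_area, x$t_min_area, x$final_relative_area))
  cat(sprintf("  minimum constituent value over run: %.3g (positivity)\n",
              x$min_constituent))
  cat(sprintf("  final max effective-strain Frobenius norm: %.4g\n",
              x$final_max_strain_norm))
  invisible(x)
}

#' @export
plot.graft_sim <- function(x, ...) {
  graphics::plot(x$times, x$relative_area, type = "l",
                 xlab = "time (days)", ylab = "relative surface area",
                 ylim = range(c(x$relative_area, 1)), ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Write a field snapshot as a legacy ASCII VTK unstructured grid
#'
#' @param snapshot one element of a \code{graft_sim}'s \code{snapshots} list
#'   (or a list with \code{cur}, \code{tri} and nodal fields).
#' @param path output file (.vtk).
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(snapshot, path) {
  co <- snapshot$cur; tri <- snapshot$tri
  n <- nrow(co); m <- nrow(tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "morphograft snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", co[, 1], co[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", tri[, 1] - 1L, tri[, 2] - 1L,
                     tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (f in c("N", "M", "c", "rho")) {
    writeLines(c(sprintf("SCALARS %s double 1", f), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.10g", snapshot[[f]]), con)
  }
  writeLines("VECTORS displacement double", con)
  writeLines(sprintf("%.10g %.10g 0", snapshot$u[, 1], snapshot$u[, 2]), con)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.10g %.10g 0", snapshot$v[, 1], snapshot$v[, 2]), con)
  for (k in 1:3) {
    nm <- c("eps22", "eps23", "eps33")[k]
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.10g", snapshot$eps[, k]), con)
  }
  invisible(path)
}

#' Write the time series of a simulation as CSV
#'
#' Columns: time, relative_area, min/max of each constituent, and the domain
#' maximum of the effective-strain Frobenius norm.
#'
#' @param sim a \code{graft_sim}.
#' @param path output file (.csv).
#' @return \code{path}, invisibly.
#' @export
write_timeseries_csv <- function(sim, path) {
  df <- data.frame(time = sim$times, relative_area = sim$relative_area)
  for (f in c("N", "M", "c", "rho")) {
    df[[paste0("min_", f)]] <- sim$mins[[f]]
    df[[paste0("max_", f)]] <- sim$maxs[[f]]
  }
  df$max_strain_norm <- sim$strain_norm
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
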