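# Independent reference computations for verification: the spatially
# homogeneous ODE reduction of the full model (all gradients and velocities
# zero), integrated with a generic stiff solver entirely separate from the
# finite-element engine.

#' Integrate the spatially homogeneous reduction
#'
#' With all spatial derivatives and velocities zero the model collapses to
#' the pointwise system dN/dt = R_N, dM/dt = R_M, dc/dt = R_c,
#' drho/dt = R_rho together with the scalar strain decay
#' de/dt = -zeta (N + eta_II M) c / (1 + a_c_III c) e.  Integrated with a
#' stiff solver (deSolve::lsoda) at tight tolerance; used as the independent
#' oracle for the finite-element engine.
#'
#' @param init named list or vector with \code{N}, \code{M}, \code{c},
#'   \code{rho} and optionally \code{e} (default 0); non-negative.
#' @param params a \code{model_parameters} object.
#' @param t_end end time, days.
#' @param times optional explicit output times (days); default 201 points.
#' @param rtol,atol solver tolerances.
#' @return matrix with columns \code{time}, \code{N}, \code{M}, \code{c},
#'   \code{rho}, \code{e}.
#' @export
integrate_homogeneous <- function(init, params, t_end,
                                  times = NULL, rtol = 1e-10, atol = NULL) {
  y0 <- c(N = init$N, M = init$M, c = init$c, rho = init$rho,
          e = if (is.null(init$e)) 0 else init$e)
  if (any(y0[1:4] < 0)) stop("initial state must be non-negative")
  if (is.null(times)) times <- seq(0, t_end, length.out = 201)
  if (is.null(atol)) {
    atol <- c(N = 1e-8 * max(params$N_bar, 1), M = 1e-8 * max(params$N_bar, 1),
              c = 1e-10 * max(params$c_w, 1e-12),
              rho = 1e-10 * max(params$rho_bar, 1e-12), e = 1e-14)
  }
  rhs <- function(t, y, parms) {
    st <- list(N = max(y[1], 0), M = max(y[2], 0),
               c = max(y[3], 0), rho = max(y[4], 0))
    k <- parms$zeta * (st$N + parms$eta_II * st$M) * st$c /
      (1 + parms$a_c_III * st$c)
    list(c(reaction_fibroblasts(st, parms),
           reaction_myofibroblasts(st, parms),
           reaction_signal(st, parms),
           reaction_collagen(st, parms),
           -k * y[5]))
  }
  out <- deSolve::lsoda(y0, times, rhs, parms = params,
                        rtol = rtol, atol = atol)
  unclass(out)
}

#' Compare the finite-element engine to the homogeneous ODE oracle
#'
#' Runs the engine with spatially uniform initial fields (so all spatial
#' terms vanish identically) and the Dirichlet constraints released, and
#' returns the maximum over time and fields of the relative deviation from
#' the independently integrated ODE reduction.
#'
#' @param mesh a \code{graft_mesh}.
#' @param params a \code{model_parameters} object.
#' @param init uniform initial values (named list: N, M, c, rho).
#' @param t_end end time, days.
#' @param n_check number of comparison epochs.
#' @param tol engine step tolerance; the default is tight because the global
#'   bias of the split scheme accumulates roughly linearly in it.
#' @param ... further settings forwarded to the engine (\code{dt0}, ...).
#' @return maximum relative deviation (floored denominator per field scale).
#' @export
compare_fem_to_ode <- function(mesh, params, init, t_end,
                               n_check = 20, tol = 5e-5, ...) {
  times <- seq(0, t_end, length.out = n_check + 1)
  ode <- integrate_homogeneous(init, params, t_end, times = times)
  n <- nrow(mesh$ref)
  st <- initial_state(mesh, params)
  st$N <- rep(init$N, n); st$M <- rep(init$M, n)
  st$c <- rep(init$c, n); st$rho <- rep(init$rho, n)
  run <- fem_run(mesh, st, params, t_end = t_end, epochs = times[-1],
                 dirichlet = FALSE, tol = tol, ...)
  dev <- 0
  floors <- c(N = 1e-6 * params$N_bar + 1e-12, M = 1e-6 * params$N_bar + 1e-12,
              c = 1e-6 * max(params$c_w, 1e-12),
              rho = 1e-6 * params$rho_bar + 1e-12)
  for (i in seq_along(run$epochs)) {
    snap <- run$snapshots[[i]]
    row <- ode[which.min(abs(ode[, "time"] - run$epochs[i])), ]
    for (f in c("N", "M", "c", "rho")) {
      d <- max(abs(snap[[f]] - row[[f]])) / (abs(row[[f]]) + floors[[f]])
      dev <- max(dev, d)
    }
  }
  dev
}
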