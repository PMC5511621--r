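# Dimensional parameter set (units: cm, day, g, cells) and the
# equilibrium-consistency completion of dependent rate constants.

#' Names of all model parameters
#'
#' @return Character vector of the field names of a \code{model_parameters}
#'   object, in canonical order.
#' @keywords internal
parameter_names <- function() {
  c(
    # (myo)fibroblast kinetics
    "r_F", "r_F_max", "a_c_I", "kappa_F", "q", "k_F", "delta_N", "delta_M",
    # cell transport
    "D_F", "chi_F",
    # signalling molecule
    "k_c", "eta_I", "eta_II", "a_c_II", "a_c_III", "a_c_IV", "delta_c", "D_c",
    # collagen
    "k_rho", "k_rho_max", "delta_rho",
    # mechanics
    "mu_1", "mu_2", "nu", "E_I", "xi", "R_const", "zeta", "rho_t",
    # equilibria and initial-condition constants
    "N_bar", "M_bar", "c_bar", "rho_bar", "c_w", "I_w",
    # graft geometry
    "s1", "s2", "theta_r"
  )
}

#' Default model parameters
#'
#' Returns the package's default dimensional parameter set (units cm, day, g,
#' cells).  The rate of morphoelastic change \code{zeta} and the MMP-secretion
#' inhibition coefficient \code{a_c_III} default to the published reference
#' values (9e2 cm^6/(cells g day) and 2e8 cm^3/g); the graft shape defaults to
#' the rotated square with \code{s1 = 2.5} cm, \code{s2 = 0.10} cm and
#' \code{theta_r = pi/4}.  The remaining constants are transcribed from the
#' companion wound-contraction model family of the same authors.  The
#' dependent rates \code{delta_N} and \code{k_rho} are completed so that the
#' unwounded state (\code{N_bar}, \code{M_bar}, \code{c_bar}, \code{rho_bar})
#' is an exact fixed point of the reaction system (see
#' \code{\link{derive_equilibrium_parameters}}).
#'
#' @param complete logical; complete the dependent parameters so the unwounded
#'   equilibrium is a fixed point (default \code{TRUE}).
#' @return A validated object of class \code{model_parameters} (a named list).
#' @export
#' @examples
#' p <- default_parameters()
#' p$zeta
#' max(abs(unlist(reaction_residuals(p))))
default_parameters <- function(complete = TRUE) {
  p <- list(
    r_F     = 0.924,   # 1/(day (cells/cm^3)^q)
    r_F_max = 2.0,
    a_c_I   = 1e-8,    # g/cm^3
    kappa_F = 1e-6,    # cm^3/cells
    q       = -0.42,
    k_F     = 1.08e7,  # cm^3/(g day)
    delta_N = NA_real_, # derived
    delta_M = 6e-2,    # 1/day
    D_F     = 1e-7,    # cm^5/(cells day)
    chi_F   = 2e-3,    # cm^5/(g day)
    k_c     = 4e-13,   # g/(cells day)
    eta_I   = 2.0,
    eta_II  = 0.5,
    a_c_II  = 1e-8,    # g/cm^3
    a_c_III = 2e8,     # cm^3/g
    a_c_IV  = 1e-9,    # g/cm^3
    delta_c = 5e-4,    # cm^6/(cells g day)
    D_c     = 2.9e-3,  # cm^2/day
    k_rho   = NA_real_, # derived
    k_rho_max = 10.0,
    delta_rho = 6e-6,  # cm^6/(cells g day)
    mu_1    = 1e2,     # N day/cm^2 (shear viscosity)
    mu_2    = 1e2,     # N day/cm^2 (bulk viscosity)
    nu      = 0.49,
    E_I     = 3.2e1,   # N/(cm^2 (g/cm^3)^(1/2))
    xi      = 1e-2,    # N/cm^2 per (cells/cm^3) per effective (g/cm^3)^-1
    R_const = 0.3,     # g/cm^3
    zeta    = 9e2,     # cm^6/(cells g day)
    rho_t   = 1.02,    # g/cm^3
    N_bar   = 1e4,     # cells/cm^3
    M_bar   = 0,       # cells/cm^3
    c_bar   = 0,       # g/cm^3
    rho_bar = 0.1,     # g/cm^3
    c_w     = 1e-8,    # g/cm^3
    I_w     = 0.2,
    s1      = 2.5,     # cm
    s2      = 0.10,    # cm
    theta_r = pi / 4   # rad
  )
  class(p) <- "model_parameters"
  if (complete) {
    p <- derive_equilibrium_parameters(p, unknowns = c("delta_N", "k_rho"))
  } else {
    # leave the derived slots NA; validation is deferred until completion
    p
  }
}

#' Load model parameters from a structured config file
#'
#' Reads a flat key/value YAML file (keys exactly the parameter names; values
#' in the cm/day/g/cells unit convention), fills unspecified keys from the
#' package defaults, validates all invariants and, optionally, completes the
#' dependent parameters.
#'
#' @param source path to a YAML file, or a YAML string.
#' @param complete logical; run \code{\link{derive_equilibrium_parameters}}
#'   with the default unknowns after loading (default \code{FALSE}: the file
#'   is taken at face value and only validated).
#' @return A validated \code{model_parameters} object.
#' @export
load_parameters <- function(source, complete = FALSE) {
  vals <- if (length(source) == 1L && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("parameter config must be a flat key/value mapping")
  unknown <- setdiff(names(vals), parameter_names())
  if (length(unknown) > 0L) {
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  }
  p <- unclass(default_parameters(complete = TRUE))
  for (k in names(vals)) {
    v <- vals[[k]]
    # YAML leaves exponent forms like "9e2" as strings; coerce them
    if (is.character(v) && length(v) == 1L) {
      v <- suppressWarnings(as.numeric(v))
    }
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", k, "' must be a single finite number")
    }
    p[[k]] <- as.numeric(v)
  }
  class(p) <- "model_parameters"
  if (complete) {
    p <- derive_equilibrium_parameters(p, unknowns = c("delta_N", "k_rho"))
  }
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks non-negativity of all rates, densities, concentrations and moduli,
#' the bounds 0 < nu < 1/2, 0 <= I_w <= 1, s2 > 0 and kappa_F * N_bar < 1.
#' Stops with the offending field and bound on violation.
#'
#' @param p a \code{model_parameters} object (possibly with NA derived slots).
#' @return \code{p}, invisibly.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "model_parameters"))
  missing <- setdiff(parameter_names(), names(p))
  if (length(missing) > 0L) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  nonneg <- setdiff(parameter_names(), c("q", "theta_r", "nu", "I_w", "s2"))
  for (k in nonneg) {
    v <- p[[k]]
    if (!is.na(v) && v < 0) stop(k, " must be >= 0 (got ", v, ")")
  }
  if (!(p$nu > 0 && p$nu < 0.5)) stop("nu out of (0, 0.5) (got ", p$nu, ")")
  if (!(p$I_w >= 0 && p$I_w <= 1)) stop("I_w out of [0, 1] (got ", p$I_w, ")")
  if (!(p$s2 > 0)) stop("s2 must be > 0 (got ", p$s2, ")")
  if (!(p$kappa_F * p$N_bar < 1)) {
    stop("kappa_F * N_bar must be < 1 (got ", p$kappa_F * p$N_bar, ")")
  }
  invisible(p)
}

#' Reaction residuals at the unwounded equilibrium
#'
#' Evaluates the four reaction terms R_N, R_M, R_c, R_rho at the state
#' (N_bar, M_bar, c_bar, rho_bar).  A consistent parameter set makes all four
#' vanish.
#'
#' @param p a \code{model_parameters} object.
#' @return Named list with components \code{R_N}, \code{R_M}, \code{R_c},
#'   \code{R_rho} (units of the respective balance equations).
#' @export
reaction_residuals <- function(p) {
  st <- list(N = p$N_bar, M = p$M_bar, c = p$c_bar, rho = p$rho_bar)
  list(
    R_N   = reaction_fibroblasts(st, p),
    R_M   = reaction_myofibroblasts(st, p),
    R_c   = reaction_signal(st, p),
    R_rho = reaction_collagen(st, p)
  )
}

#' Complete dependent parameters from the equilibrium constraints
#'
#' The unwounded state (N_bar, M_bar, c_bar, rho_bar) must be a fixed point of
#' the reaction system; a handful of rate constants are therefore consequences
#' of the others.  Given a partial parameter set and the names of up to three
#' unknown fields, solves R_N = R_M = R_c = R_rho = 0 for the unknowns
#' (closed-form where the structure permits, damped Newton otherwise) and
#' returns the completed set.  With the default M_bar = c_bar = 0 equilibrium
#' the myofibroblast and signal residuals vanish identically and the active
#' constraints give delta_N and k_rho in closed form.
#'
#' @param partial a \code{model_parameters} object; the fields named in
#'   \code{unknowns} may be NA.
#' @param unknowns character vector (length 1--3) of field names to solve for.
#' @return Completed, validated \code{model_parameters}; every equilibrium
#'   residual below 1e-10 in its natural units.
#' @export
derive_equilibrium_parameters <- function(partial,
                                          unknowns = c("delta_N", "k_rho")) {
  stopifnot(inherits(partial, "model_parameters"))
  if (length(unknowns) < 1L || length(unknowns) > 3L) {
    stop("between 1 and 3 unknowns are supported")
  }
  bad <- setdiff(unknowns, parameter_names())
  if (length(bad) > 0L) stop("unknown field name(s): ", paste(bad, collapse = ", "))
  p <- partial

  resid_active <- function(p) {
    r <- reaction_residuals(p)
    # scale residuals to comparable magnitudes (per-capita / per-mass rates)
    c(R_N   = r$R_N   / max(p$N_bar, 1),
      R_M   = r$R_M   / max(p$N_bar, 1),
      R_c   = r$R_c   / max(p$c_bar, p$c_w, 1e-30),
      R_rho = r$R_rho / max(p$rho_bar, 1e-30))
  }

  # initial guess for NA unknowns: closed-form values of the default structure
  guess <- function(p, k) {
    switch(k,
      delta_N = p$r_F * (1 - p$kappa_F * p$N_bar) * p$N_bar^p$q,
      k_rho   = p$delta_rho * p$rho_bar^2,
      delta_M = 1e-2,
      1e-3)
  }
  for (k in unknowns) {
    if (is.na(p[[k]])) p[[k]] <- guess(p, k)
  }

  x0 <- unname(unlist(p[unknowns]))
  fn <- function(x) {
    q <- p
    for (i in seq_along(unknowns)) q[[unknowns[i]]] <- x[i]
    sum(resid_active(q)^2)
  }
  # Damped Newton on the residual vector via numeric Jacobian; the system is
  # nearly linear in the usual unknowns, so this converges in a few steps.
  x <- x0
  for (iter in 1:60) {
    q <- p; for (i in seq_along(unknowns)) q[[unknowns[i]]] <- x[i]
    r <- resid_active(q)
    if (max(abs(r)) < 1e-14) break
    J <- matrix(0, 4, length(x))
    for (i in seq_along(x)) {
      h <- max(abs(x[i]), 1e-8) * 1e-7
      xp <- x; xp[i] <- xp[i] + h
      qp <- p; for (j in seq_along(unknowns)) qp[[unknowns[j]]] <- xp[j]
      J[, i] <- (resid_active(qp) - r) / h
    }
    step <- tryCatch(qr.solve(J, -r), error = function(e) NULL)
    if (is.null(step)) {
      # fall back to least squares via the normal equations
      step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(length(x)),
                             -crossprod(J, r))[, 1],
                       error = function(e) stop("equilibrium system is singular"))
    }
    lam <- 1
    f0 <- sum(r^2)
    repeat {
      xn <- x + lam * step
      if (fn(xn) <= f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    x <- x + lam * step
  }
  for (i in seq_along(unknowns)) p[[unknowns[i]]] <- unname(x[i])

  res <- reaction_residuals(p)
  if (max(abs(unlist(res))) >= 1e-10) {
    stop("equilibrium system not solvable for (",
         paste(unknowns, collapse = ", "), "): max residual ",
         format(max(abs(unlist(res)))))
  }
  rate_like <- intersect(unknowns, setdiff(parameter_names(), c("q", "theta_r")))
  for (k in rate_like) {
    if (p[[k]] < 0) stop("negative solution for rate '", k, "': ", p[[k]])
  }
  validate_parameters(p)
  p
}

#' Export a completed parameter set as JSON
#'
#' Writes the full parameter set to a JSON file for provenance alongside
#' simulation output.
#'
#' @param p a \code{model_parameters} object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_parameters_json <- function(p, path) {
  stopifnot(inherits(p, "model_parameters"))
  jsonlite::write_json(unclass(p)[parameter_names()], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Morphoelastic graft model parameters (cm / day / g / cells)\n")
  v <- unlist(unclass(x)[parameter_names()])
  cat(paste0(format(names(v), width = 10), " = ",
             format(v, digits = 6, scientific = TRUE)), sep = "\n")
  invisible(x)
}
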