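# Moving-grid (Lagrangian) P1 finite-element engine.
#
# One time step = semi-implicit momentum solve (viscous + linearised elastic
# stiffness implicit, traction and accumulated elastic stress explicit)
# -> strain / displacement / mesh update -> reaction-transport update of the
# four constituents with geometric dilution, Patankar source splitting and a
# Zalesak flux-corrected-transport limiter.  Steps are controlled by
# step-doubling local error estimation.

# accumulate per-element contributions onto nodes
acc_nodes <- function(vals, ids, n) {
  s <- rowsum(vals, ids)
  out <- numeric(n)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# lumped mass vector on given coordinates (P1: area/3 to each vertex)
lumped_mass <- function(coords, tri) {
  g <- element_geometry(coords, tri)
  if (any(g$area <= 0)) {
    stop("inverted element (non-positive area): id ",
         which(g$area <= 0)[1])
  }
  w <- g$area / 3
  acc_nodes(c(w, w, w), c(tri[, 1], tri[, 2], tri[, 3]), nrow(coords))
}

# scalar diffusion stiffness with per-element coefficient kappa_el
stiffness_scalar <- function(geo, tri, kappa_el) {
  n_el <- nrow(tri)
  ii <- jj <- xx <- vector("list", 9)
  idx <- 1
  for (a in 1:3) for (b in 1:3) {
    ii[[idx]] <- tri[, a]
    jj[[idx]] <- tri[, b]
    xx[[idx]] <- kappa_el * geo$area *
      (geo$gx[, a] * geo$gx[, b] + geo$gy[, a] * geo$gy[, b])
    idx <- idx + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(max(tri), max(tri)))
}

# divergence-form advection matrix for a per-element constant velocity field
# (ay, az): weak form -int z a . grad(phi_i), entries K[i, j] per element
advection_scalar <- function(geo, tri, ay, az) {
  n_el <- nrow(tri)
  ii <- jj <- xx <- vector("list", 9)
  idx <- 1
  for (a in 1:3) {
    adg <- ay * geo$gx[, a] + az * geo$gy[, a]
    for (b in 1:3) {
      ii[[idx]] <- tri[, a]
      jj[[idx]] <- tri[, b]
      xx[[idx]] <- -adg * geo$area / 3
      idx <- idx + 1
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(max(tri), max(tri)))
}

# vector (2 dof/node) stiffness for isotropic stress 2 mu sym(grad v)
# + lam tr(grad v) I, with per-element moduli; dof ordering (vy_1..vy_n,
# vz_1..vz_n)
stiffness_vector <- function(geo, tri, mu_el, lam_el, n_nodes) {
  ii <- jj <- xx <- vector("list", 36)
  idx <- 1
  g <- list(geo$gx, geo$gy)
  for (a in 1:3) for (b in 1:3) {
    for (di in 1:2) for (dj in 1:2) {
      gai <- g[[di]][, a]; gbj <- g[[dj]][, b]
      gaj <- g[[dj]][, a]; gbi <- g[[di]][, b]
      val <- geo$area * (lam_el * gai * gbj + mu_el * gaj * gbi +
                           if (di == dj) mu_el * (geo$gx[, a] * geo$gx[, b] +
                                                  geo$gy[, a] * geo$gy[, b])
                           else 0)
    ii[[idx]] <- tri[, a] + (di - 1L) * n_nodes
    jj[[idx]] <- tri[, b] + (dj - 1L) * n_nodes
    xx[[idx]] <- val
    idx <- idx + 1
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2L * n_nodes, 2L * n_nodes))
}

# element average of a nodal field
elem_mean <- function(z, tri) {
  (z[tri[, 1]] + z[tri[, 2]] + z[tri[, 3]]) / 3
}

# lumped L2 projection of per-element constants to nodes
project_to_nodes <- function(vals_el, geo, tri, m_lumped) {
  w <- geo$area / 3
  acc_nodes(c(w * vals_el, w * vals_el, w * vals_el),
            c(tri[, 1], tri[, 2], tri[, 3]), length(m_lumped)) / m_lumped
}

# per-element gradient of a nodal scalar field (constant on P1 elements)
elem_grad <- function(z, geo, tri) {
  cbind(geo$gx[, 1] * z[tri[, 1]] + geo$gx[, 2] * z[tri[, 2]] +
          geo$gx[, 3] * z[tri[, 3]],
        geo$gy[, 1] * z[tri[, 1]] + geo$gy[, 2] * z[tri[, 2]] +
          geo$gy[, 3] * z[tri[, 3]])
}

# nodal velocity gradient L (columns L22, L23, L32, L33) by lumped projection
velocity_gradient_nodes <- function(v, geo, tri, m_lumped) {
  gy <- elem_grad(v[, 1], geo, tri)
  gz <- elem_grad(v[, 2], geo, tri)
  L22 <- gy[, 1]; L23 <- gy[, 2]; L32 <- gz[, 1]; L33 <- gz[, 2]
  cbind(L22 = project_to_nodes(L22, geo, tri, m_lumped),
        L23 = project_to_nodes(L23, geo, tri, m_lumped),
        L32 = project_to_nodes(L32, geo, tri, m_lumped),
        L33 = project_to_nodes(L33, geo, tri, m_lumped))
}

#' Assemble the discrete transport operators
#'
#' Builds, on the current (moved) coordinates, the lumped mass vector, the
#' per-constituent transport operators (nonlinear diffusion plus chemotactic
#' drift for the cells, Fickian diffusion for the signal, none for the
#' immobile collagen) and their low-order positivity-preserving counterparts
#' obtained by adding symmetric algebraic diffusion that cancels every
#' positive off-diagonal entry.
#'
#' @param mesh a \code{graft_mesh}.
#' @param state a \code{state_fields} object sized to the mesh.
#' @param params a \code{model_parameters} object.
#' @return list with \code{m} (lumped mass), per-constituent lists
#'   (\code{K} high-order operator, \code{KL} low-order operator, \code{D}
#'   the artificial-diffusion edge list \code{i}, \code{j}, \code{d}),
#'   and the element geometry.
#' @export
assemble_transport <- function(mesh, state, params) {
  tri <- mesh$tri
  geo <- element_geometry(mesh$cur, tri)
  if (any(geo$area <= 0)) {
    stop("inverted element (non-positive area): id ", which(geo$area <= 0)[1])
  }
  n <- nrow(mesh$cur)
  m <- lumped_mass(mesh$cur, tri)

  F_el <- elem_mean(state$N + state$M, tri)
  # element-constant signal gradient for the chemotactic drift
  gc <- elem_grad(state$c, geo, tri)
  gcy <- gc[, 1]; gcz <- gc[, 2]

  K_cell_diff <- stiffness_scalar(geo, tri, params$D_F * F_el)
  K_chemo <- advection_scalar(geo, tri, params$chi_F * gcy, params$chi_F * gcz)
  K_cell <- K_cell_diff + K_chemo
  K_c <- stiffness_scalar(geo, tri, rep(params$D_c, nrow(tri)))

  low_order <- function(K) {
    Kt <- methods::as(K, "TsparseMatrix")
    i <- Kt@i + 1L; j <- Kt@j + 1L; x <- Kt@x
    off <- i != j
    # symmetric artificial diffusion d_ij = max(0, K_ij, K_ji)
    Ksym <- pmax(K, Matrix::t(K))
    Kst <- methods::as(methods::as(Ksym, "generalMatrix"), "TsparseMatrix")
    si <- Kst@i + 1L; sj <- Kst@j + 1L; sx <- Kst@x
    keep <- si < sj & sx > 0
    di <- si[keep]; dj <- sj[keep]; dd <- sx[keep]
    if (length(di) == 0) return(list(KL = K, edges = list(i = integer(0),
                                                          j = integer(0),
                                                          d = numeric(0))))
    Dart <- Matrix::sparseMatrix(
      i = c(di, dj, di, dj), j = c(dj, di, di, dj),
      x = c(-dd, -dd, dd, dd), dims = dim(K))
    list(KL = K + Dart, edges = list(i = di, j = dj, d = dd))
  }
  lo_cell <- low_order(K_cell)
  lo_c <- low_order(K_c)
  Kzero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
  list(
    m = m, geo = geo,
    N = list(K = K_cell, KL = lo_cell$KL, edges = lo_cell$edges),
    M = list(K = K_cell, KL = lo_cell$KL, edges = lo_cell$edges),
    c = list(K = K_c, KL = lo_c$KL, edges = lo_c$edges),
    rho = list(K = Kzero, KL = Kzero,
               edges = list(i = integer(0), j = integer(0), d = numeric(0)))
  )
}

#' Zalesak flux-corrected-transport limiter
#'
#' Given the non-negative low-order solution and the antidiffusive edge fluxes
#' whose unlimited application would reproduce the high-order candidate,
#' limits each flux so the corrected field stays within the local low-order
#' bounds (hence non-negative) while remaining conservative (the fluxes are
#' applied antisymmetrically).
#'
#' @param z_low low-order nodal solution (non-negative).
#' @param m lumped mass vector.
#' @param edges list with integer vectors \code{i}, \code{j} and flux values
#'   \code{f}: the raw antidiffusive flux from node \code{j} into node
#'   \code{i} (mass units; node \code{j} loses \code{f}).
#' @param fixed logical mask of Dirichlet-constrained nodes; fluxes touching
#'   them are suppressed and their values kept.
#' @return corrected nodal field.
#' @export
apply_fct <- function(z_low, m, edges, fixed = NULL) {
  n <- length(z_low)
  if (length(edges$i) == 0) return(z_low)
  i <- edges$i; j <- edges$j; f <- edges$f
  if (!is.null(fixed)) {
    drop <- fixed[i] | fixed[j]
    i <- i[drop == FALSE]; j <- j[drop == FALSE]; f <- f[drop == FALSE]
    if (length(i) == 0) return(z_low)
  }
  # local bounds from the low-order solution over the flux stencil
  zmax <- z_low; zmin <- z_low
  # pairwise max/min over neighbours
  t1 <- tapply(z_low[j], i, max); k1 <- as.integer(names(t1))
  zmax[k1] <- pmax(zmax[k1], as.numeric(t1))
  t2 <- tapply(z_low[i], j, max); k2 <- as.integer(names(t2))
  zmax[k2] <- pmax(zmax[k2], as.numeric(t2))
  t3 <- tapply(z_low[j], i, min); k3 <- as.integer(names(t3))
  zmin[k3] <- pmin(zmin[k3], as.numeric(t3))
  t4 <- tapply(z_low[i], j, min); k4 <- as.integer(names(t4))
  zmin[k4] <- pmin(zmin[k4], as.numeric(t4))

  Pp <- numeric(n); Pm <- numeric(n)
  fp <- pmax(f, 0); fm <- pmax(-f, 0)
  add_at <- function(vec, idx, vals) {
    s <- tapply(vals, idx, sum); k <- as.integer(names(s))
    vec[k] <- vec[k] + as.numeric(s); vec
  }
  Pp <- add_at(Pp, i, fp); Pp <- add_at(Pp, j, fm)  # incoming positive mass
  Pm <- add_at(Pm, i, fm); Pm <- add_at(Pm, j, fp)  # outgoing mass
  Qp <- m * (zmax - z_low)
  Qm <- m * (z_low - zmin)
  Rp <- ifelse(Pp > 0, pmin(1, Qp / Pp), 1)
  Rm <- ifelse(Pm > 0, pmin(1, Qm / Pm), 1)
  alpha <- ifelse(f >= 0, pmin(Rp[i], Rm[j]), pmin(Rm[i], Rp[j]))
  corr <- numeric(n)
  corr <- add_at(corr, i, alpha * f)
  corr <- add_at(corr, j, -alpha * f)
  out <- z_low + corr / m
  pmax(out, 0)  # guard against roundoff at the zero bound
}

# one transport update of all four constituents over dt on the current mesh;
# z_star are the dilution-rescaled old values, dirichlet is a list of fixed
# values per constituent (or NULL to release the boundary)
transport_step <- function(mesh, state, params, dt, m_new, z_star, ops,
                           dirichlet) {
  n <- nrow(mesh$cur)
  src <- split_sources(state, params)
  out <- list()
  for (f in c("N", "M", "c", "rho")) {
    K <- ops[[f]]$KL
    prod <- src[[f]]$prod
    loss <- src[[f]]$loss
    A <- K + Matrix::Diagonal(n, m_new / dt + m_new * loss)
    b <- m_new * z_star[[f]] / dt + m_new * prod
    fixed <- NULL
    if (!is.null(dirichlet) && !is.null(dirichlet[[f]])) {
      fixed <- mesh$boundary
      bval <- dirichlet[[f]]
      # constrained rows implement the boundary value exactly
      mask <- as.numeric(!fixed)
      A <- Matrix::Diagonal(n, mask) %*% A + Matrix::Diagonal(n, 1 - mask)
      b[fixed] <- bval
    }
    z_low <- as.numeric(Matrix::solve(A, b))
    z_low <- pmax(z_low, 0)
    e <- ops[[f]]$edges
    if (length(e$i) > 0) {
      flux <- dt * e$d * (z_low[e$i] - z_low[e$j])
      z_new <- apply_fct(z_low, m_new, list(i = e$i, j = e$j, f = flux),
                         fixed = fixed)
    } else {
      z_new <- z_low
    }
    out[[f]] <- z_new
  }
  out
}

#' Semi-implicit momentum solve
#'
#' Advances the displacement velocity by one step of the momentum balance
#' \code{rho_t Dv/Dt + rho_t v div v = div sigma + div psi} on the current
#' coordinates.  The viscous stress and a linearisation of the elastic stress
#' increment (\code{dt * (1 - tr eps) * elastic stiffness}) are implicit; the
#' accumulated elastic stress and the myofibroblast traction enter explicitly
#' through their weak-form divergence (integration by parts; boundary term
#' dropped on the constrained boundary).  Boundary velocities are pinned to
#' zero.
#'
#' @param mesh a \code{graft_mesh}.
#' @param state a \code{state_fields} object.
#' @param params a \code{model_parameters} object.
#' @param dt step size, days.
#' @param keep_inertia include the explicit \code{rho_t v [div v]} advective
#'   momentum term (default TRUE); FALSE gives the quasi-static variant of
#'   the same solve.
#' @param dirichlet_v constrain the boundary velocity to zero (default TRUE).
#' @return n x 2 matrix of updated velocities, cm/day.
#' @export
solve_momentum <- function(mesh, state, params, dt, keep_inertia = TRUE,
                           dirichlet_v = TRUE) {
  tri <- mesh$tri
  n <- nrow(mesh$cur)
  geo <- element_geometry(mesh$cur, tri)
  if (any(geo$area <= 0)) {
    stop("inverted element (non-positive area): id ", which(geo$area <= 0)[1])
  }
  m <- lumped_mass(mesh$cur, tri)

  # implicit viscous stiffness: sigma_v = mu_1 sym(L) + mu_2 tr(L) I
  K_visc <- stiffness_vector(geo, tri, rep(params$mu_1 / 2, nrow(tri)),
                             rep(params$mu_2, nrow(tri)), n)
  # implicit linearised elastic increment
  rho_el <- elem_mean(state$rho, tri)
  tre_el <- elem_mean(tensor_trace(state$eps), tri)
  E_el <- youngs_modulus(rho_el, params)
  fac <- pmax(1 - tre_el, 0)
  mu_e <- E_el / (2 * (1 + params$nu))
  lam_e <- E_el * params$nu / ((1 + params$nu) * (1 - 2 * params$nu))
  K_el <- stiffness_vector(geo, tri, dt * fac * mu_e, dt * fac * lam_e, n)

  # explicit internal forces: accumulated elastic stress + traction psi
  sig <- cauchy_stress(state$eps, NULL, state$rho, params)
  psi <- traction_stress(state$M, state$rho, params)
  s22 <- elem_mean(sig[, 1] + psi, tri)
  s23 <- elem_mean(sig[, 2], tri)
  s33 <- elem_mean(sig[, 3] + psi, tri)
  fy <- fz <- NULL; ids <- NULL
  for (a in 1:3) {
    fy <- c(fy, geo$area * (s22 * geo$gx[, a] + s23 * geo$gy[, a]))
    fz <- c(fz, geo$area * (s23 * geo$gx[, a] + s33 * geo$gy[, a]))
    ids <- c(ids, tri[, a])
  }
  Fint <- c(acc_nodes(fy, ids, n), acc_nodes(fz, ids, n))

  A <- K_visc + K_el +
    Matrix::Diagonal(2 * n, rep(params$rho_t * m / dt, 2))
  b <- rep(params$rho_t * m / dt, 2) * c(state$v[, 1], state$v[, 2]) - Fint
  if (keep_inertia) {
    divv <- velocity_gradient_nodes(state$v, geo, tri, m)
    dv <- divv[, 1] + divv[, 4]
    b <- b - params$rho_t * rep(m, 2) * c(state$v[, 1], state$v[, 2]) *
      rep(dv, 2)
  }
  if (dirichlet_v) {
    mask <- rep(as.numeric(!mesh$boundary), 2)
    Dm <- Matrix::Diagonal(2 * n, mask)
    A <- Dm %*% A %*% Dm + Matrix::Diagonal(2 * n, 1 - mask)
    b <- b * mask
  }
  v <- as.numeric(Matrix::solve(A, b))
  if (any(!is.finite(v))) stop("singular momentum system")
  cbind(v[1:n], v[(n + 1):(2 * n)])
}

#' Strain, displacement and mesh update
#'
#' Advances the nodal effective strain with the morphoelastic evolution law
#' (growth tensor plus Jaumann-corrected kinematics), the displacement by
#' \code{u <- u + dt v}, and moves the mesh with the material
#' (\code{cur = ref + u}).
#'
#' @param mesh a \code{graft_mesh}.
#' @param state a \code{state_fields} with the freshly solved velocity.
#' @param params a \code{model_parameters} object.
#' @param dt step size, days.
#' @return list with updated \code{mesh} and \code{state}.
#' @export
update_strain <- function(mesh, state, params, dt) {
  tri <- mesh$tri
  geo <- element_geometry(mesh$cur, tri)
  m <- lumped_mass(mesh$cur, tri)
  L <- velocity_gradient_nodes(state$v, geo, tri, m)
  G <- growth_tensor(state$eps, state, params)
  de <- strain_rate(state$eps, L, G)
  state$eps <- state$eps + dt * de
  state$u <- state$u + dt * state$v
  mesh$cur <- mesh$ref + state$u
  list(mesh = mesh, state = state)
}

# one full split step of size dt; returns list(mesh, state) or NULL on failure
step_once <- function(mesh, state, params, dt, opts) {
  ok <- tryCatch({
    m_old <- lumped_mass(mesh$cur, mesh$tri)
    state$v <- solve_momentum(mesh, state, params, dt,
                              keep_inertia = opts$keep_inertia,
                              dirichlet_v = opts$dirichlet_v)
    up <- update_strain(mesh, state, params, dt)
    mesh <- up$mesh; state <- up$state
    m_new <- lumped_mass(mesh$cur, mesh$tri)
    # geometric dilution: exact discrete counterpart of Dz/Dt = -z div v
    ratio <- m_old / m_new
    z_star <- list(N = state$N * ratio, M = state$M * ratio,
                   c = state$c * ratio, rho = state$rho * ratio)
    ops <- assemble_transport(mesh, state, params)
    zn <- transport_step(mesh, state, params, dt, m_new, z_star, ops,
                         opts$dirichlet_values)
    state$N <- zn$N; state$M <- zn$M; state$c <- zn$c; state$rho <- zn$rho
    list(mesh = mesh, state = state)
  }, error = function(e) NULL)
  if (is.null(ok)) return(NULL)
  flat <- c(ok$state$N, ok$state$M, ok$state$c, ok$state$rho,
            ok$state$eps, ok$state$u, ok$state$v)
  if (any(!is.finite(flat))) return(NULL)
  ok
}

# local (Richardson) extrapolation of the step-doubling pair: 2 * half - full
# cancels the leading first-order splitting error; constituents are clipped at
# zero and the combination is discarded if it would fold the moved grid
richardson_combine <- function(half, full, ref) {
  s <- half$state
  for (f in c("N", "M", "c", "rho")) {
    s[[f]] <- pmax(2 * half$state[[f]] - full$state[[f]], 0)
  }
  for (f in c("u", "v", "eps")) {
    s[[f]] <- 2 * half$state[[f]] - full$state[[f]]
  }
  mesh <- half$mesh
  mesh$cur <- mesh$ref + s$u
  geo_ok <- tryCatch(all(element_geometry(mesh$cur, mesh$tri)$area > 0),
                     error = function(e) FALSE)
  if (!geo_ok) return(list(mesh = half$mesh, state = half$state))
  list(mesh = mesh, state = s)
}

# scaled maximum difference between two states (local error estimate); the
# velocity is an auxiliary of the viscous-dominated momentum balance and is
# controlled through u and eps, so it is not part of the norm
state_error <- function(s1, s2, scales) {
  max(
    max(abs(s1$N - s2$N)) / scales["N"],
    max(abs(s1$M - s2$M)) / scales["M"],
    max(abs(s1$c - s2$c)) / scales["c"],
    max(abs(s1$rho - s2$rho)) / scales["rho"],
    max(abs(s1$eps - s2$eps)) / scales["eps"],
    max(abs(s1$u - s2$u)) / scales["u"]
  )
}

#' Create a step-size controller
#'
#' @param dt0 initial step, days.
#' @param tol local error tolerance (scaled, dimensionless).
#' @param dt_min,dt_max step bounds, days.
#' @param grow maximum growth factor per accepted step.
#' @return list of class \code{step_controller}.
#' @export
step_controller <- function(dt0 = 0.1, tol = 1e-3, dt_min = 1e-6,
                            dt_max = 5, grow = 1.5) {
  ctl <- list(dt = dt0, tol = tol, dt_min = dt_min, dt_max = dt_max,
              grow = grow)
  class(ctl) <- "step_controller"
  ctl
}

#' Advance the coupled system by one adaptive step
#'
#' Performs one step of the full split scheme with step-doubling error
#' control: the solution from two half steps is compared against one full
#' step; if the scaled difference is within tolerance the (more accurate)
#' two-half-step solution is accepted and the step may grow, otherwise the
#' step is rejected and halved.
#'
#' @param controller a \code{step_controller}.
#' @param mesh a \code{graft_mesh}.
#' @param state a \code{state_fields}.
#' @param params a \code{model_parameters} object.
#' @param opts engine options (see \code{\link{fem_run}}).
#' @return list with \code{mesh}, \code{state}, \code{controller},
#'   \code{accepted} flag, \code{err} estimate and the step size \code{dt}
#'   that was attempted.
#' @export
advance <- function(controller, mesh, state, params, opts) {
  dt <- controller$dt
  if (dt < controller$dt_min) {
    stop("time step underflow: dt = ", dt, " < dt_min = ", controller$dt_min)
  }
  full <- step_once(mesh, state, params, dt, opts)
  h1 <- step_once(mesh, state, params, dt / 2, opts)
  half <- if (is.null(h1)) NULL else
    step_once(h1$mesh, h1$state, params, dt / 2, opts)
  if (is.null(full) || is.null(half)) {
    controller$dt <- max(dt / 2, controller$dt_min / 2)
    return(list(mesh = mesh, state = state, controller = controller,
                accepted = FALSE, err = Inf, dt = dt))
  }
  err <- state_error(full$state, half$state, opts$scales)
  if (err <= controller$tol) {
    fac <- if (err > 0) min(controller$grow, max(0.3, 0.8 * sqrt(controller$tol / err)))
           else controller$grow
    controller$dt <- min(controller$dt_max, dt * fac)
    acc <- richardson_combine(half, full, mesh$ref)
    list(mesh = acc$mesh, state = acc$state, controller = controller,
         accepted = TRUE, err = err, dt = dt)
  } else {
    controller$dt <- max(dt / 2, controller$dt_min / 2)
    list(mesh = mesh, state = state, controller = controller,
         accepted = FALSE, err = err, dt = dt)
  }
}

# default scaled-error denominators per field
error_scales <- function(params) {
  c(N = params$N_bar, M = params$N_bar,
    c = max(params$c_w, params$c_bar, 1e-12),
    rho = params$rho_bar, eps = 0.2, u = 1, v = 0.05)
}

#' Run the finite-element engine
#'
#' Low-level time loop: advances the coupled system from the given state to
#' \code{t_end}, landing exactly on the requested epochs, optionally adapting
#' the mesh, and recording per-step diagnostics.  Most users should call
#' \code{\link{simulate_graft}} instead.
#'
#' @param mesh a \code{graft_mesh}.
#' @param state a \code{state_fields}.
#' @param params a \code{model_parameters} object.
#' @param t_end end time, days.
#' @param epochs times (days) at which full field snapshots are stored.
#' @param tracers optional \code{tracer_set}; the displaced polygon area is
#'   recorded at every accepted step.
#' @param dirichlet constrain N, M, c to their equilibrium boundary values
#'   (default TRUE; FALSE releases the boundary, used by the ODE-oracle
#'   comparison).
#' @param tol,dt0,dt_max step-controller settings.
#' @param quasi_static drop the advective inertial term (default FALSE).
#' @param refine_every adapt the mesh every this many accepted steps
#'   (0 = keep the initial mesh, the default).
#' @param refine_threshold indicator threshold forwarded to
#'   \code{\link{refine_recoarsen}}.
#' @param max_level refinement level cap.
#' @param checkpoint_path optional path; an RDS checkpoint of the latest
#'   accepted state is maintained there.
#' @return list with \code{times}, \code{relative_area}, per-field min/max
#'   traces, \code{strain_norm} trace (domain maximum Frobenius norm),
#'   \code{epochs}, \code{snapshots} (list of field lists), final
#'   \code{mesh}, \code{state}, and the step \code{log} (matrix).
#' @export
fem_run <- function(mesh, state, params, t_end, epochs = numeric(0),
                    tracers = NULL, dirichlet = TRUE, tol = 1e-3,
                    dt0 = 0.05, dt_max = 5, quasi_static = FALSE,
                    refine_every = 0L, refine_threshold = 0.25,
                    max_level = 2L, checkpoint_path = NULL) {
  opts <- list(
    keep_inertia = !quasi_static,
    dirichlet_v = TRUE,
    dirichlet_values = if (isTRUE(dirichlet))
      list(N = params$N_bar, M = params$M_bar, c = params$c_bar) else NULL,
    scales = error_scales(params)
  )
  ctl <- step_controller(dt0 = dt0, tol = tol, dt_max = dt_max)
  epochs <- sort(unique(epochs[epochs > 0 & epochs <= t_end]))
  t <- 0
  ref_area <- if (!is.null(tracers)) abs(polygon_area(tracers$ref)) else NA
  times <- 0
  rel_area <- if (!is.null(tracers)) 1 else NA_real_
  mins <- list(); maxs <- list()
  fields <- c("N", "M", "c", "rho")
  for (f in fields) { mins[[f]] <- min(state[[f]]); maxs[[f]] <- max(state[[f]]) }
  strain_norm <- 0
  snapshots <- list()
  snap_times <- numeric(0)
  log <- NULL
  n_acc <- 0L
  next_epoch <- if (length(epochs) > 0) 1L else 0L

  while (t < t_end - 1e-9) {
    target <- if (next_epoch > 0 && next_epoch <= length(epochs))
      epochs[next_epoch] else t_end
    ctl$dt <- min(ctl$dt, target - t, t_end - t)
    res <- advance(ctl, mesh, state, params, opts)
    log <- rbind(log, c(t = t, dt = res$dt, err = res$err,
                        accepted = as.numeric(res$accepted),
                        n_nodes = nrow(mesh$ref)))
    ctl <- res$controller
    if (!res$accepted) next
    mesh <- res$mesh; state <- res$state
    t <- t + res$dt
    n_acc <- n_acc + 1L

    if (refine_every > 0L && n_acc %% refine_every == 0L) {
      rr <- refine_recoarsen(mesh, state, refine_threshold,
                             max_level = max_level)
      mesh <- rr$mesh; state <- rr$state
    }
    times <- c(times, t)
    if (!is.null(tracers)) {
      rel_area <- c(rel_area,
                    tracer_polygon_area(tracers, mesh, state) / ref_area)
    }
    for (f in fields) {
      mins[[f]] <- c(mins[[f]], min(state[[f]]))
      maxs[[f]] <- c(maxs[[f]], max(state[[f]]))
    }
    strain_norm <- c(strain_norm,
                     max(sqrt(state$eps[, 1]^2 + 2 * state$eps[, 2]^2 +
                                state$eps[, 3]^2)))
    if (next_epoch > 0 && next_epoch <= length(epochs) &&
        abs(t - epochs[next_epoch]) < 1e-9) {
      snapshots[[length(snapshots) + 1L]] <-
        list(N = state$N, M = state$M, c = state$c, rho = state$rho,
             u = state$u, v = state$v, eps = state$eps,
             cur = mesh$cur, ref = mesh$ref, tri = mesh$tri, time = t)
      snap_times <- c(snap_times, t)
      next_epoch <- next_epoch + 1L
    }
    if (!is.null(checkpoint_path)) {
      saveRDS(list(t = t, mesh = mesh, state = state, controller = ctl),
              checkpoint_path)
    }
  }
  list(times = times, relative_area = rel_area, mins = mins, maxs = maxs,
       strain_norm = strain_norm, epochs = snap_times, snapshots = snapshots,
       mesh = mesh, state = state, log = log)
}
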