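# helper: minimal hand-built meshes for operator fixtures
single_triangle_mesh <- function() {
  mesh <- list(ref = rbind(c(0, 0), c(1, 0), c(0, 2)),
               cur = rbind(c(0, 0), c(1, 0), c(0, 2)),
               tri = matrix(c(1, 2, 3), 1, 3),
               boundary = rep(TRUE, 3),
               level = 0L, parent_def = matrix(NA_integer_, 1, 3),
               anc = vector("list", 1), half_width = 2)
  class(mesh) <- "graft_mesh"
  mesh
}

uniform_state <- function(mesh, N, M, c, rho) {
  n <- nrow(mesh$ref)
  st <- list(N = rep(N, n), M = rep(M, n), c = rep(c, n), rho = rep(rho, n),
             u = matrix(0, n, 2), v = matrix(0, n, 2),
             eps = plane_tensor(rep(0, n), 0, 0))
  class(st) <- "state_fields"
  st
}

# parameters with every kinetic, flux and growth coefficient switched off
inert_params <- function() {
  p <- params_default
  for (k in c("r_F", "k_F", "delta_N", "delta_M", "k_c", "delta_c",
              "k_rho", "delta_rho", "D_F", "chi_F", "D_c", "zeta", "xi"))
    p[[k]] <- 0
  p
}

test_that("transport assembly matches the P1 closed forms", {
  p <- params_default
  mesh <- single_triangle_mesh()
  st <- uniform_state(mesh, p$N_bar, 0, 1e-8, p$rho_bar)
  ops <- assemble_transport(mesh, st, p)
  # unit-area triangle: lumped mass diagonal = area/3 per node
  expect_equal(ops$m, rep(1 / 3, 3), tolerance = 1e-14)
  # constant field in the kernel of every transport operator
  ones <- rep(1, 3)
  expect_lt(max(abs(as.numeric(ops$c$K %*% ones))), 1e-12)
  expect_lt(max(abs(as.numeric(ops$N$K %*% ones))), 1e-12)
  # immobile collagen: no diffusion stiffness at all
  expect_identical(Matrix::nnzero(ops$rho$K), 0L)
  # inverted element reported by id
  bad <- mesh; bad$cur <- bad$cur[c(2, 1, 3), ]
  st_b <- st
  expect_error(assemble_transport(bad, st_b, p), "inverted element")
})

test_that("Zalesak limiter matches the brute-force oracle on a 3-node fixture", {
  m <- rep(1, 3)
  z <- c(0.6, 1.0, 0.0)
  edges <- list(i = c(1L, 2L), j = c(2L, 3L), f = c(0.5, -0.3))
  out <- apply_fct(z, m, edges)
  # brute-force oracle: largest admissible flux fractions under the
  # low-order local bounds (stencil min/max including the node itself)
  zmin <- c(0.6, 0.0, 0.0); zmax <- c(1.0, 1.0, 1.0)
  best <- c(0, 0)
  for (a1 in seq(0, 1, by = 0.01)) for (a2 in seq(0, 1, by = 0.01)) {
    zz <- z + c(a1 * 0.5, -a1 * 0.5 - a2 * 0.3, a2 * 0.3)
    if (all(zz >= zmin - 1e-12 & zz <= zmax + 1e-12) &&
        sum(c(a1, a2)) > sum(best)) best <- c(a1, a2)
  }
  expect_equal(best, c(0.8, 1), tolerance = 1e-9)
  expect_equal(out, z + c(0.4, -0.7, 0.3), tolerance = 1e-12)
  # conservation of the lumped-mass integral
  expect_equal(sum(m * out), sum(m * z), tolerance = 1e-12)
  # zero fluxes: low-order solution returned exactly
  out0 <- apply_fct(z, m, list(i = 1L, j = 2L, f = 0))
  expect_identical(out0, z)
  # small fluxes (all ratios >= 1): unlimited high-order candidate
  small <- list(i = c(1L, 2L), j = c(2L, 3L), f = c(0.05, -0.05))
  expect_equal(apply_fct(z, m, small), z + c(0.05, -0.1, 0.05),
               tolerance = 1e-14)
  # a flux that would drive a node negative is fully cancelled
  neg <- apply_fct(c(0, 0.5, 0.5), m, list(i = 2L, j = 1L, f = 0.4))
  expect_identical(neg[1], 0)
  expect_gte(min(neg), 0)
})

test_that("momentum solve is at rest without forcing and pins the boundary", {
  p <- params_default
  mesh <- build_mesh(10, 2.5)
  st <- uniform_state(mesh, p$N_bar, 0, 0, p$rho_bar)
  v <- solve_momentum(mesh, st, p, dt = 0.5)
  expect_identical(max(abs(v)), 0)
  # spatially uniform traction: discrete divergence vanishes in the interior
  st$M <- rep(500, nrow(mesh$ref))
  v2 <- solve_momentum(mesh, st, p, dt = 0.5)
  expect_lt(max(abs(v2)), 1e-12)
  expect_identical(max(abs(v2[mesh$boundary, ])), 0)
  # non-uniform traction moves the interior but never the boundary
  st$M <- 2000 * exp(-rowSums(mesh$ref^2) / 8)
  v3 <- solve_momentum(mesh, st, p, dt = 0.5)
  expect_gt(max(abs(v3)), 1e-6)
  expect_identical(max(abs(v3[mesh$boundary, ])), 0)
  # quasi-static and full modes agree at these parameter scales
  v4 <- solve_momentum(mesh, st, p, dt = 0.5, keep_inertia = FALSE)
  expect_equal(v3, v4, tolerance = 1e-6)
})

test_that("strain and mesh update follow the kinematics", {
  p <- inert_params()
  mesh <- build_mesh(10, 2.5)
  st <- uniform_state(mesh, p$N_bar, 0, 0, p$rho_bar)
  # v = 0, G = 0: strain frozen, mesh static
  up <- update_strain(mesh, st, p, dt = 1)
  expect_identical(up$state$eps, st$eps)
  expect_identical(up$mesh$cur, mesh$cur)
  # homogeneous stretching L = d I: tr(eps) grows by 2 d dt (1 - tr eps)
  d <- 0.01; dt <- 0.5
  st$v <- d * mesh$cur
  up2 <- update_strain(mesh, st, p, dt = dt)
  tre <- up2$state$eps[, 1] + up2$state$eps[, 3]
  expect_equal(tre, rep(2 * d * dt, length(tre)), tolerance = 1e-10)
  # bookkeeping: current coordinates = reference + displacement
  expect_equal(up2$mesh$cur, mesh$ref + up2$state$u, tolerance = 1e-14)
})

test_that("moving grid transports nodal values exactly under rigid motion", {
  p <- inert_params()
  mesh <- build_mesh(10, 2.5)
  st <- uniform_state(mesh, 5000, 100, 1e-8, 0.2)
  set.seed(11)
  st$c <- runif(nrow(mesh$ref), 0, 1e-8)  # arbitrary profile
  m_old <- morphograft:::lumped_mass(mesh$cur, mesh$tri)
  # rigid translation of the whole grid
  mesh2 <- mesh; mesh2$cur <- mesh$cur + matrix(c(0.3, -0.2),
                                                nrow(mesh$cur), 2, byrow = TRUE)
  m_new <- morphograft:::lumped_mass(mesh2$cur, mesh2$tri)
  ratio <- m_old / m_new
  expect_equal(ratio, rep(1, length(ratio)), tolerance = 1e-12)
  ops <- assemble_transport(mesh2, st, p)
  zs <- list(N = st$N * ratio, M = st$M * ratio, c = st$c * ratio,
             rho = st$rho * ratio)
  zn <- morphograft:::transport_step(mesh2, st, p, dt = 0.5, m_new, zs, ops,
                                     NULL)
  expect_equal(zn$c, st$c, tolerance = 1e-10)
  expect_equal(zn$N, st$N, tolerance = 1e-10)
})

test_that("adaptive stepping accepts at equilibrium and rejects corrupt states", {
  p <- params_default
  mesh <- build_mesh(10, 2.5)
  st <- uniform_state(mesh, p$N_bar, p$M_bar, p$c_bar, p$rho_bar)
  opts <- list(keep_inertia = TRUE, dirichlet_v = TRUE,
               dirichlet_values = list(N = p$N_bar, M = p$M_bar, c = p$c_bar),
               scales = morphograft:::error_scales(p))
  ctl <- step_controller(dt0 = 0.5, tol = 1e-3, dt_max = 5)
  res <- advance(ctl, mesh, st, p, opts)
  expect_true(res$accepted)
  expect_lt(res$err, 1e-8)
  expect_gt(res$controller$dt, 0.5)  # grows toward the cap
  # equilibrium is preserved through the accepted step
  expect_lt(max(abs(res$state$N - p$N_bar)) / p$N_bar, 1e-10)
  # a corrupted field forces rejection and a halved step
  st_bad <- st; st_bad$rho[5] <- NaN
  res2 <- advance(ctl, mesh, st_bad, p, opts)
  expect_false(res2$accepted)
  expect_equal(res2$controller$dt, 0.25)
  # step underflow aborts with a diagnostic
  ctl_small <- step_controller(dt0 = 1e-9, dt_min = 1e-6)
  expect_error(advance(ctl_small, mesh, st, p, opts), "underflow")
})

test_that("constituent mass is conserved without fluxes, reactions or motion", {
  p <- inert_params()
  p$D_c <- 2.9e-3  # diffusion on, everything else off
  mesh <- build_mesh(10, 2.5)
  st <- uniform_state(mesh, 5000, 0, 0, 0.2)
  st$c <- 1e-8 * exp(-rowSums(mesh$ref^2) / 4)
  run <- fem_run(mesh, st, p, t_end = 20, dirichlet = FALSE, tol = 1e-3,
                 dt0 = 0.5)
  m0 <- morphograft:::lumped_mass(mesh$cur, mesh$tri)
  m1 <- morphograft:::lumped_mass(run$mesh$cur, run$mesh$tri)
  expect_equal(sum(m1 * run$state$c), sum(m0 * st$c), tolerance = 1e-8)
  expect_equal(sum(m1 * run$state$N), sum(m0 * st$N), tolerance = 1e-10)
  expect_gte(min(run$state$c), 0)
  # diffusion flattened the peak but moved nothing outside
  expect_lt(max(run$state$c), max(st$c))
})
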