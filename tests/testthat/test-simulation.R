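test_that("relative area responds to displacement as pure geometry dictates", {
  p <- params_default
  mesh <- build_mesh(10, 2)
  st <- initial_state(mesh, p)
  tr <- place_tracers(p, 2)
  expect_identical(relative_area(tr, mesh, st), 1)
  # uniform shrink by 0.8 about the origin: area scales with the square
  st$u <- -0.2 * mesh$ref
  expect_equal(relative_area(tr, mesh, st), 0.64, tolerance = 1e-10)
  # rigid rotation is an isometry
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  st$u <- mesh$ref %*% t(R) - mesh$ref
  expect_equal(relative_area(tr, mesh, st), 1, tolerance = 1e-10)
})

test_that("unwounded control stays at equilibrium through the full pipeline", {
  p <- params_default
  sim <- simulate_graft(p, t_end = 15, target_edge = 4, unwounded = TRUE,
                        tol = 1e-3, dt0 = 0.5)
  expect_lt(max(abs(unlist(sim$mins$N) - p$N_bar)) / p$N_bar, 1e-6)
  expect_lt(max(abs(unlist(sim$maxs$rho) - p$rho_bar)) / p$rho_bar, 1e-6)
  expect_lt(max(abs(sim$relative_area - 1)), 1e-9)
  expect_lt(sim$strain_norm[length(sim$strain_norm)], 1e-9)
})

test_that("runs are deterministic and snapshots land on the epochs", {
  p <- params_default
  s1 <- simulate_graft(p, t_end = 6, target_edge = 5, tol = 2e-3,
                       epochs = c(3, 6))
  s2 <- simulate_graft(p, t_end = 6, target_edge = 5, tol = 2e-3,
                       epochs = c(3, 6))
  expect_identical(s1$relative_area, s2$relative_area)
  expect_identical(s1$state$N, s2$state$N)
  expect_equal(s1$epochs, c(3, 6))
  expect_identical(length(s1$snapshots), 2L)
  expect_equal(s1$snapshots[[2]]$time, 6)
  # relative_area starts exactly at 1 and time is strictly increasing
  expect_identical(s1$relative_area[1], 1)
  expect_true(all(diff(s1$times) > 0))
})

test_that("contraction run respects the point symmetry of the problem", {
  p <- params_default
  sim <- simulate_graft(p, t_end = 12, target_edge = 4, tol = 2e-3)
  ref <- sim$mesh$ref
  # index of the point-reflected node
  key <- paste(round(ref[, 1], 8), round(ref[, 2], 8))
  mirror <- match(paste(round(-ref[, 1], 8), round(-ref[, 2], 8)), key)
  expect_false(anyNA(mirror))
  st <- sim$state
  expect_lt(max(abs(st$N - st$N[mirror])) / p$N_bar, 1e-8)
  expect_lt(max(abs(st$c - st$c[mirror])) / p$c_w, 1e-8)
  expect_lt(max(abs(st$u + st$u[mirror, ])), 1e-8)  # u is odd under reflection
  expect_lt(max(abs(st$eps - st$eps[mirror, ])), 1e-8)
})

test_that("scenario wrapper applies overrides and sweeps tabulate per config", {
  sim <- run_scenario(list(overrides = list(zeta = 0), t_end = 4,
                           target_edge = 5, tol = 5e-3))
  expect_identical(sim$params$zeta, 0)
  expect_error(run_scenario(list(overrides = list(nu = 0.7), t_end = 2,
                                 target_edge = 5)), "nu")
  expect_error(sweep_scenarios(9e2, 2e8, t_end = 2), "at least 2")
})

test_that("writers emit valid VTK and CSV artifacts", {
  p <- params_default
  sim <- simulate_graft(p, t_end = 4, target_edge = 5, tol = 5e-3,
                        epochs = 4)
  tv <- tempfile(fileext = ".vtk")
  write_vtk(sim$snapshots[[1]], tv)
  lines <- readLines(tv)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  n <- nrow(sim$mesh$ref); m <- nrow(sim$mesh$tri)
  expect_true(sprintf("POINTS %d double", n) %in% lines)
  expect_true(sprintf("CELLS %d %d", m, 4 * m) %in% lines)
  expect_true("SCALARS rho double 1" %in% lines)
  tc <- tempfile(fileext = ".csv")
  write_timeseries_csv(sim, tc)
  df <- utils::read.csv(tc)
  expect_identical(nrow(df), length(sim$times))
  expect_true(all(c("time", "relative_area", "min_N", "max_strain_norm")
                  %in% names(df)))
  # checkpointing keeps a restartable snapshot of the latest accepted state
  tk <- tempfile(fileext = ".rds")
  sim2 <- simulate_graft(p, t_end = 2, target_edge = 5, tol = 5e-3,
                         checkpoint_path = tk)
  chk <- readRDS(tk)
  expect_equal(chk$t, 2)
  expect_identical(chk$state$N, sim2$state$N)
})

test_that("halving the grid spacing barely moves the day-50 relative area", {
  p <- params_default
  coarse <- simulate_graft(p, t_end = 50, target_edge = 2.5, tol = 2e-3)
  fine <- simulate_graft(p, t_end = 50, target_edge = 1.25, tol = 1e-3)
  a1 <- coarse$relative_area[length(coarse$relative_area)]
  a2 <- fine$relative_area[length(fine$relative_area)]
  expect_lt(abs(a1 - a2) / a2, 0.02)
})
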