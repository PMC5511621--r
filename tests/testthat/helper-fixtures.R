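# shared fixtures: completed default parameters and a fast variant used where
# concrete dynamics are needed on tiny meshes
params_default <- default_parameters()

# a single reference point-state away from equilibrium, used by kinetics tests
point_state <- function(N = 2000, M = 500, c = 1e-8, rho = 0.1) {
  list(N = N, M = M, c = c, rho = rho)
}

# random non-negative point states under a fixed seed
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(N = runif(1, 0, 2e4), M = runif(1, 0, 1e4),
         c = runif(1, 0, 5e-8), rho = runif(1, 0.01, 1))
  })
}

expect_conforming <- function(mesh) {
  expect_true(morphograft:::mesh_is_conforming(mesh))
}
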