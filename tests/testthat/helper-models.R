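# shared fixtures built in code

ou_model <- function(alpha_x = 1, alpha_y = 5, beta = 1, gamma = 1) {
  make_model("overdamped", ou_potential(alpha_x, alpha_y),
             beta = beta, gamma = gamma)
}

# short cached trajectories (per test session) to avoid repeated simulation
.traj_cache <- new.env(parent = emptyenv())

cached_traj <- function(key, fn) {
  if (is.null(.traj_cache[[key]])) .traj_cache[[key]] <- fn()
  .traj_cache[[key]]
}

ou_traj <- function(n_steps = 5e5, dt = 1e-3, seed = 101) {
  key <- sprintf("ou_%g_%g_%d", n_steps, dt, seed)
  cached_traj(key, function()
    simulate_em(ou_model(), dt = dt, n_steps = n_steps, seed = seed))
}

lemon_traj <- function(n_steps = 1e6, dt = 1e-3, seed = 202) {
  key <- sprintf("lemon_%g_%g_%d", n_steps, dt, seed)
  cached_traj(key, function()
    simulate_em(make_model("overdamped", lemon_slice_potential(), 1, 1),
                dt = dt, n_steps = n_steps, seed = seed))
}

random_points <- function(n, d, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n * d, sd = sd), n, d)
}
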