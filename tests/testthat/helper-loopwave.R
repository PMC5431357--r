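# Shared fixtures and small oracles for the test suite.

p3 <- function(r = 1, rho = 1, mu = 1.8, N = 3) model_params(r, rho, mu, N)

# total variation distance between two pmfs on a shared support
tvd <- function(p, q) 0.5 * sum(abs(p - q))

# Synthetic three-phase rotating trajectory with known period: the leading
# node holds `high` of `nbar` and advances one node every period/3.
make_rotating_traj <- function(period, t_max, dt = 0.05, nbar = 1000,
                               high = 0.8) {
  times <- seq(0, t_max, by = dt)
  phase <- floor((times %% period) / (period / 3)) # 0, 1, 2
  states <- matrix(nbar * (1 - high) / 2, length(times), 3)
  for (i in seq_along(times)) states[i, phase[i] + 1L] <- nbar * high
  colnames(states) <- paste0("n_", 1:3)
  structure(list(times = times, states = states, params = p3(),
                 status = "completed", seed = NA_integer_, sample_dt = dt,
                 extinction_time = NA_real_),
            class = "bdm_trajectory")
}

# Constant-occupancy trajectory (uniform or fully collapsed etc.)
make_constant_traj <- function(n, t_max = 20, dt = 0.1) {
  times <- seq(0, t_max, by = dt)
  states <- matrix(rep(n, each = length(times)), length(times), length(n))
  colnames(states) <- paste0("n_", seq_along(n))
  structure(list(times = times, states = states, params = p3(),
                 status = "completed", seed = NA_integer_, sample_dt = dt,
                 extinction_time = NA_real_),
            class = "bdm_trajectory")
}
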