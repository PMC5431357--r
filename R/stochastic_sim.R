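#' Transition propensities of a state
#'
#' Per-node rates of the four event types, evaluated at a configuration
#' `n = (n_1, ..., n_N)`:
#' forward migration `r * n_i * (1 + rho)/2`, backward migration
#' `r * n_i * (1 - rho)/2`, birth `mu * n_i`, and death
#' `mu * n_tot / Z` at each populated node (`Z` = number of populated nodes;
#' the death process cannot operate at an empty node).  The total birth and
#' total death rates are both `mu * n_tot`, so the total population is a
#' critical birth-death process with conserved mean.
#'
#' @param state A [system_state()] or bare population vector.
#' @param params A [model_params()] object.
#' @return A list with numeric vectors `forward`, `backward`, `birth`,
#'   `death` (length `N`) and the scalar `total`.  An empty system returns
#'   all-zero rates.
#' @examples
#' propensities(c(2, 1, 0), model_params(1, 1, 2))
#' @export
propensities <- function(state, params) {
  stopifnot(inherits(params, "bdm_params"))
  n <- if (inherits(state, "bdm_state")) state$n else as.numeric(state)
  stopifnot(length(n) == params$N, all(n >= 0))
  fwd <- params$r * n * (1 + params$rho) / 2
  bwd <- params$r * n * (1 - params$rho) / 2
  birth <- params$mu * n
  ntot <- sum(n)
  Z <- sum(n > 0)
  death <- if (Z > 0) ifelse(n > 0, params$mu * ntot / Z, 0) else rep(0, length(n))
  list(forward = fwd, backward = bwd, birth = birth, death = death,
       total = sum(c(fwd, bwd, birth, death)))
}

#' One exact stochastic step
#'
#' Draws an exponential waiting time with the total propensity and one event
#' in proportion to the individual propensities, and applies it to the state.
#' Uses R's RNG stream (`set.seed()` controls it).
#'
#' @inheritParams propensities
#' @param state A [system_state()].
#' @return If the system is extinct (total rate 0), `list(absorbed = TRUE,
#'   state = state)`.  Otherwise `list(absorbed = FALSE, event = list(kind,
#'   node, t), state = <new state>)` where `kind` is one of
#'   `"migrate_forward"`, `"migrate_backward"`, `"birth"`, `"death"`.
#' @export
gillespie_step <- function(state, params) {
  stopifnot(inherits(state, "bdm_state"), inherits(params, "bdm_params"))
  p <- propensities(state, params)
  flat <- c(p$forward, p$backward, p$birth, p$death)
  total <- sum(flat)
  if (total <= 0)
    return(list(absorbed = TRUE, state = state))
  tau <- stats::rexp(1L, rate = total)
  u <- stats::runif(1L) * total
  j <- which(u <= cumsum(flat))[1L]
  if (is.na(j)) j <- length(flat) # guard against roundoff at the top end
  N <- params$N
  kind <- c("migrate_forward", "migrate_backward", "birth", "death")[(j - 1L) %/% N + 1L]
  node <- (j - 1L) %% N + 1L
  n <- state$n
  if (kind == "migrate_forward") {
    n[node] <- n[node] - 1; k2 <- node %% N + 1L; n[k2] <- n[k2] + 1
  } else if (kind == "migrate_backward") {
    n[node] <- n[node] - 1; k2 <- (node - 2L) %% N + 1L; n[k2] <- n[k2] + 1
  } else if (kind == "birth") {
    n[node] <- n[node] + 1
  } else {
    n[node] <- n[node] - 1
  }
  new_state <- system_state(n, t = state$t + tau)
  list(absorbed = FALSE,
       event = list(kind = kind, node = node, t = new_state$t),
       state = new_state)
}

#' Exact stochastic realization of the loop process
#'
#' Runs the direct-method (Gillespie) simulation from a given initial
#' configuration and samples the trajectory on a regular time grid
#' (piecewise-constant between events).  Reproducible bit-for-bit given
#' `(params, initial, seed)`.  Extinction before `t_max` truncates the
#' trajectory and flags it `"extinct"`; it is an absorbing outcome of the
#' critical total-population dynamics, not an error.
#'
#' @inheritParams propensities
#' @param initial Per-node initial populations (length `N`).
#' @param t_max Final time (> 0).
#' @param seed Integer RNG seed, recorded in the result.
#' @param sample_dt Sampling interval (> 0).
#' @param record_events If `TRUE`, keep the full event log (can be large).
#' @return An object of class `bdm_trajectory`: list with `times`, `states`
#'   (matrix, one row per sample, columns `n_1..n_N`), `params`, `seed`,
#'   `status` (`"completed"` or `"extinct"`), `extinction_time`,
#'   `event_counts`, and optionally `events`.
#' @examples
#' tr <- simulate_bdm(model_params(1, 1, 1.8), c(100, 100, 100),
#'                    t_max = 10, seed = 1)
#' @export
simulate_bdm <- function(params, initial, t_max, seed, sample_dt = 0.1,
                         record_events = FALSE) {
  stopifnot(inherits(params, "bdm_params"),
            length(initial) == params$N, all(initial >= 0),
            all(initial == round(initial)),
            is.numeric(t_max), t_max > 0,
            is.numeric(sample_dt), sample_dt > 0)
  set.seed(as.integer(seed))
  res <- gillespie_run_cpp(as.numeric(initial), params$r, params$rho,
                           params$mu, t_max, sample_dt, record_events)
  colnames(res$states) <- paste0("n_", seq_len(params$N))
  if (record_events && !is.null(res$events))
    res$events$kind <- c("migrate_forward", "migrate_backward",
                         "birth", "death")[res$events$kind + 1L]
  structure(list(times = res$times, states = res$states, params = params,
                 seed = as.integer(seed), status = res$status,
                 extinction_time = res$extinction_time,
                 event_counts = res$event_counts,
                 events = if (record_events) res$events else NULL,
                 initial = as.numeric(initial), sample_dt = sample_dt),
            class = "bdm_trajectory")
}

#' @export
print.bdm_trajectory <- function(x, ...) {
  cat(sprintf("Stochastic trajectory: N = %d nodes, %d samples (dt = %g), status %s\n",
              ncol(x$states), length(x$times), x$sample_dt, x$status))
  cat(sprintf("  params: r = %g, rho = %g, mu = %g; seed %d\n",
              x$params$r, x$params$rho, x$params$mu, x$seed))
  cat("  events:", paste(names(x$event_counts),
                         format(x$event_counts, big.mark = ","), collapse = ", "), "\n")
  invisible(x)
}

#' Ensemble of independent realizations
#'
#' Runs `n_reps` independent simulations (replicate `k` uses seed
#' `seed_base + k`) on a shared sampling grid and returns per-time,
#' per-node means and variances across replicates.  Replicates that go
#' extinct contribute zero populations from their extinction time onward, so
#' the ensemble mean total remains an unbiased estimate of the conserved
#' mean.
#'
#' @inheritParams simulate_bdm
#' @param n_reps Number of replicates (>= 1).
#' @param seed_base Base seed; replicate `k` uses `seed_base + k`.
#' @return An object of class `bdm_ensemble`: list with `times`, `mean`,
#'   `var` (matrices time x node), `trajectories`, `statuses`, `seeds`.
#' @export
ensemble_bdm <- function(params, initial, n_reps, seed_base, t_max,
                         sample_dt = 0.1) {
  stopifnot(n_reps >= 1)
  seeds <- as.integer(seed_base) + seq_len(n_reps)
  trajs <- lapply(seeds, function(s)
    simulate_bdm(params, initial, t_max, seed = s, sample_dt = sample_dt))
  times <- seq(0, t_max, by = sample_dt)
  Tn <- length(times)
  N <- params$N
  arr <- array(0, dim = c(Tn, N, n_reps))
  for (k in seq_len(n_reps)) {
    st <- trajs[[k]]$states
    m <- min(nrow(st), Tn)
    arr[seq_len(m), , k] <- st[seq_len(m), ] # extinct tails stay at zero
  }
  mu_hat <- apply(arr, c(1, 2), mean)
  var_hat <- if (n_reps > 1) apply(arr, c(1, 2), stats::var) else
    matrix(0, Tn, N)
  colnames(mu_hat) <- colnames(var_hat) <- paste0("n_", seq_len(N))
  structure(list(times = times, mean = mu_hat, var = var_hat,
                 trajectories = trajs,
                 statuses = vapply(trajs, `[[`, "", "status"),
                 seeds = seeds, params = params),
            class = "bdm_ensemble")
}

#' @export
print.bdm_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d realizations (seeds %d..%d), %d extinct\n",
              length(x$seeds), min(x$seeds), max(x$seeds),
              sum(x$statuses == "extinct")))
  invisible(x)
}
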