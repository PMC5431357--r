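# Run configuration, scenario presets and file writers: the reproducibility
# layer binding the simulator, mean-field analysis and classifiers together.

#' Named scenario presets
#'
#' The four reference simulation settings of the three-node loop with
#' `r = 1`, `rho = 1` and 1000 particles per node, one per regime:
#' `fig2a` amorphous (`mu = 0`), `fig2b` wave (`mu = 1.8`, `theta = 0.6`),
#' `fig2c` intermittent (`mu = 2.08`, `theta = 1.16`), `fig2d` collapsed
#' (`mu = 2.2`, `theta = 1.4`).
#'
#' @param name One of `"fig2a"`, `"fig2b"`, `"fig2c"`, `"fig2d"`.
#' @param seed,outputs Passed through to [run_config()].
#' @return A [run_config()] object.
#' @export
scenario_preset <- function(name, seed = 1L, outputs = tempfile("loopwave_")) {
  mu <- switch(name,
               fig2a = 0, fig2b = 1.8, fig2c = 2.08, fig2d = 2.2,
               stop("unknown scenario preset: ", name, call. = FALSE))
  run_config(model_params(r = 1, rho = 1, mu = mu, N = 3L),
             initial = c(1000, 1000, 1000), t_max = 100, sample_dt = 0.1,
             n_reps = 1L, seed = seed, outputs = outputs, scenario = name)
}

#' Run configuration
#'
#' Validated bundle of model parameters and run settings.  Validation
#' happens before any computation starts and reports every offending field
#' at once.
#'
#' @param params A [model_params()] object.
#' @param initial Per-node initial populations.
#' @param t_max,sample_dt Simulation horizon and sampling interval.
#' @param n_reps Number of replicates.
#' @param seed Base RNG seed.
#' @param outputs Output directory.
#' @param scenario Optional preset name, recorded in metadata.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params, initial, t_max, sample_dt = 0.1, n_reps = 1L,
                       seed = 1L, outputs = tempfile("loopwave_"),
                       scenario = NULL) {
  cfg <- structure(list(params = params, initial = initial, t_max = t_max,
                        sample_dt = sample_dt, n_reps = n_reps,
                        seed = as.integer(seed), outputs = outputs,
                        scenario = scenario),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @return `validate_run_config()` returns `config` invisibly or stops with
#'   a structured message listing every invalid field.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bad <- character(0)
  p <- config$params
  if (!inherits(p, "bdm_params")) bad <- c(bad, "params: not a model_params object")
  else if (length(config$initial) != p$N ||
           any(config$initial < 0) || any(config$initial != round(config$initial)))
    bad <- c(bad, "initial: must be N non-negative integers")
  if (!is.numeric(config$t_max) || config$t_max <= 0)
    bad <- c(bad, "t_max: must be > 0")
  if (!is.numeric(config$sample_dt) || config$sample_dt <= 0)
    bad <- c(bad, "sample_dt: must be > 0")
  if (!is.numeric(config$n_reps) || config$n_reps < 1)
    bad <- c(bad, "n_reps: must be >= 1")
  if (!is.numeric(config$seed) || is.na(config$seed))
    bad <- c(bad, "seed: must be an integer")
  if (length(bad))
    stop("invalid run configuration:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(config)
}

#' Hash of a run configuration
#'
#' MD5 digest of the canonical JSON form of the configuration; embedded in
#' every output file so artifacts can be traced to their exact settings.
#'
#' @param config A [run_config()].
#' @return A hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  canon <- list(r = config$params$r, rho = config$params$rho,
                mu = config$params$mu, N = config$params$N,
                initial = config$initial, t_max = config$t_max,
                sample_dt = config$sample_dt, n_reps = config$n_reps,
                seed = config$seed)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a trajectory as CSV
#'
#' Columns `t, n_1..n_N`, preceded by comment lines embedding the
#' configuration hash and seed.
#'
#' @param traj A `bdm_trajectory`.
#' @param path Output file.
#' @param hash Configuration hash to embed (optional).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, hash = NA_character_) {
  stopifnot(inherits(traj, "bdm_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d status=%s", hash, traj$seed,
                     traj$status), con)
  df <- data.frame(t = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV file.
#' @return A data frame with column `t` and the node populations.
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Spectral summary as JSON text
#'
#' @param spec A `bdm_spectrum` from [interior_eigenvalues()].
#' @return A JSON string with fields `eigenvalues` (list of `re`, `im`),
#'   `hopf_threshold`, `is_oscillatory`.
#' @export
spectrum_json <- function(spec) {
  stopifnot(inherits(spec, "bdm_spectrum"))
  jsonlite::toJSON(list(
    eigenvalues = lapply(spec$eigenvalues,
                         function(s) list(re = Re(s), im = Im(s))),
    hopf_threshold = spec$hopf_threshold,
    is_oscillatory = spec$is_oscillatory), auto_unbox = TRUE, digits = NA)
}

#' Write a lattice distribution as CSV
#'
#' One row per enumerated state: the state tuple and its probability.
#'
#' @param P A [lattice_distribution()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(P, path) {
  stopifnot(inherits(P, "lattice_distribution"))
  df <- data.frame(P$space$states, prob = P$prob, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run a complete scenario
#'
#' Validates the configuration, runs the stochastic simulation(s), computes
#' the deterministic context (control parameter, eigenvalues, predicted
#' regime), classifies each realized trajectory, and writes all artifacts
#' into `config$outputs`: per-replicate trajectory CSVs and a metadata JSON
#' embedding the configuration hash, seeds, spectra and classifications.
#' Rerunning the same configuration (including seed) reproduces the output
#' files byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `trajectories`, `classifications`,
#'   `metadata` and `files`.
#' @export
run_scenario <- function(config) {
  validate_run_config(config)
  dir.create(config$outputs, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  hash <- config_hash(config)
  seeds <- config$seed + seq_len(config$n_reps) - 1L
  trajs <- lapply(seeds, function(s)
    simulate_bdm(p, config$initial, config$t_max, seed = s,
                 sample_dt = config$sample_dt))
  cls <- lapply(trajs, classify_regime)
  spec <- interior_eigenvalues(p)
  theta <- if (p$rho != 0 && p$N == 3L) control_parameter(p) else NA_real_
  files <- character(0)
  for (k in seq_along(trajs)) {
    f <- file.path(config$outputs, sprintf("trajectory_rep%03d.csv", k))
    write_trajectory_csv(trajs[[k]], f, hash = hash)
    files <- c(files, f)
  }
  meta <- list(
    config_hash = hash,
    scenario = config$scenario,
    params = list(r = p$r, rho = p$rho, mu = p$mu, N = p$N),
    initial = config$initial,
    t_max = config$t_max, sample_dt = config$sample_dt,
    seeds = seeds,
    theta = theta,
    eigenvalues = lapply(spec$eigenvalues,
                         function(s) list(re = Re(s), im = Im(s))),
    hopf_threshold = spec$hopf_threshold,
    predicted_regime = predict_regime(p),
    classified = vapply(cls, `[[`, "", "label"),
    statuses = vapply(trajs, `[[`, "", "status"),
    event_counts = lapply(trajs, function(tr) as.list(tr$event_counts)),
    package_version = as.character(utils::packageVersion("loopwave")))
  meta_file <- file.path(config$outputs, "metadata.json")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), meta_file)
  files <- c(files, meta_file)
  invisible(list(trajectories = trajs, classifications = cls,
                 metadata = meta, files = files))
}

#' Sweep the control parameter
#'
#' Evaluates the deterministic wave characteristics over a grid of `theta`
#' values and optionally adds stochastic estimates (frequency and amplitude
#' with their spread across replicates).  Per-point failures are recorded in
#' the `error` column and the sweep continues.
#'
#' @param config A [run_config()] supplying `r`, `rho`, initial populations
#'   and run control for the optional simulations.
#' @param thetas Numeric grid of control-parameter values.
#' @param simulate If `TRUE`, run `config$n_reps` stochastic replicates per
#'   grid point and estimate `f` and `A` from them.
#' @param write If `TRUE`, write the table to `sweep.csv` under
#'   `config$outputs`.
#' @return A data frame with columns `theta`, `mu`, `fhat`, `frequency`,
#'   `amplitude`, `exists` and, when `simulate = TRUE`, `f_sim`, `f_sim_sd`,
#'   `A_sim`, `A_sim_sd`, `n_reps_used`, plus an `error` column.
#' @export
sweep_theta <- function(config, thetas, simulate = FALSE, write = FALSE) {
  validate_run_config(config)
  if (length(thetas) == 0) {
    warning("empty theta grid: returning empty table")
    return(data.frame(theta = numeric(0), mu = numeric(0), fhat = numeric(0),
                      frequency = numeric(0), amplitude = numeric(0),
                      exists = logical(0), error = character(0)))
  }
  r <- config$params$r; rho <- config$params$rho
  rows <- lapply(thetas, function(th) {
    mu <- (th * r * abs(rho) + 3 * r) / 2
    pa <- model_params(r, rho, mu, 3L)
    row <- data.frame(theta = th, mu = mu, fhat = NA_real_,
                      frequency = NA_real_, amplitude = NA_real_,
                      exists = NA, error = NA_character_,
                      stringsAsFactors = FALSE)
    wc <- tryCatch(limit_cycle(pa), error = function(e) e)
    if (inherits(wc, "error")) {
      row$error <- conditionMessage(wc)
      return(row)
    }
    row$fhat <- wc$fhat; row$frequency <- wc$frequency
    row$amplitude <- wc$amplitude; row$exists <- wc$exists
    if (simulate) {
      ens <- ensemble_bdm(pa, config$initial, config$n_reps,
                          seed_base = config$seed, t_max = config$t_max,
                          sample_dt = config$sample_dt)
      fs <- vapply(ens$trajectories, function(tr) {
        est <- tryCatch(estimate_frequency(tr), error = function(e) NULL)
        if (is.null(est)) NA_real_ else est$frequency
      }, numeric(1))
      as_ <- vapply(ens$trajectories, function(tr)
        estimate_amplitude(tr)$amplitude, numeric(1))
      ok <- !is.na(fs)
      row$f_sim <- mean(fs[ok]); row$f_sim_sd <- stats::sd(fs[ok])
      row$A_sim <- mean(as_[ok]); row$A_sim_sd <- stats::sd(as_[ok])
      row$n_reps_used <- sum(ok)
    }
    row
  })
  out <- do.call(rbind, rows)
  if (write) {
    dir.create(config$outputs, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(config$outputs, "sweep.csv")
    con <- file(f, "w")
    writeLines(sprintf("# config_hash=%s seed=%d", config_hash(config),
                       config$seed), con)
    utils::write.csv(out, con, row.names = FALSE)
    close(con)
  }
  out
}
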