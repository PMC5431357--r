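# Observables of stochastic trajectories: occupancy fractions, regime
# classification (amorphous / wave / intermittent / collapsed), and
# frequency/amplitude estimates of the travelling disturbance.

#' Per-time occupancy fractions
#'
#' The proportion of particles at each node at every sampled time,
#' `n_i / n_tot`.  Rows sum to one.
#'
#' @param traj A `bdm_trajectory` from [simulate_bdm()].
#' @return A matrix of fractions with the same shape as `traj$states`.
#' @export
occupancy_fractions <- function(traj) {
  stopifnot(inherits(traj, "bdm_trajectory"))
  totals <- rowSums(traj$states)
  if (all(totals == 0))
    stop("no occupancy defined: trajectory is fully extinct", call. = FALSE)
  keep <- totals > 0 # extinct tail is already truncated by the simulator
  fr <- traj$states[keep, , drop = FALSE] / totals[keep]
  fr
}

# Leading-node label per sample (ties broken by lowest index).
.lead_sequence <- function(fr) max.col(fr, ties.method = "first")

# Net signed rotation of the leading-node label, in units of full loop
# revolutions (positive = forward).  Also returns the cumulative position so
# callers can segment the trajectory into cycles.
.rotation_position <- function(leads, N) {
  rl <- rle(leads)$values
  if (length(rl) < 2L) return(list(net = 0, pos = NULL, coherence = 0))
  d <- diff(rl)
  step <- ifelse(d %% N == 1, 1L, ifelse(d %% N == N - 1L, -1L, 0L))
  pos <- cumsum(step)
  # map back to sample indices of each lead change
  change_idx <- cumsum(rle(leads)$lengths)
  change_idx <- change_idx[-length(change_idx)] + 1L
  list(net = pos[length(pos)], pos = pos, change_idx = change_idx,
       coherence = abs(pos[length(pos)]) / length(d))
}

#' Classify a stochastic trajectory into a regime
#'
#' Deterministic decision rule matching the phenomenology of the four
#' regimes: an *amorphous* trajectory keeps all occupancy fractions near 1/3
#' with no coherent rotation; a *wave* trajectory shows the leading-node
#' label completing full cyclic rotations while each node periodically
#' empties; a *collapsed* trajectory holds almost all particles at a single
#' node persistently; an *intermittent* trajectory alternates between
#' wave-like motion and collapse epochs (particles temporarily lodging at a
#' single node).  Extinct trajectories are labelled `"extinct"`.
#'
#' The rule, applied after discarding a burn-in:
#' *wave evidence* is at least two net full revolutions of the leading-node
#' label together with recurring node-emptying events (occupancy below
#' `empty_threshold`); a *collapse epoch* is a run with maximum occupancy
#' above `collapse_threshold` sustained for at least one reference period
#' (`window`, defaulting to the mean-field cycle period — motion stalled for
#' a full period is lodging, not a wave crest passing).  Wave evidence with
#' no collapse epoch gives `"wave"`; both together give `"intermittent"`,
#' unless a single collapse epoch runs from before the last completed
#' rotation to the end of the trajectory and covers at least half of it, in
#' which case the early rotations were the transient and the label is
#' `"collapsed"`.  Without wave evidence: persistent collapse in the second
#' half gives `"collapsed"`, a flat occupancy profile gives `"amorphous"`.
#'
#' @param traj A `bdm_trajectory`.
#' @param params Optional [model_params()] used to compute the reference
#'   period from [limit_cycle()]; defaults to the trajectory's own.
#' @param window Reference duration for a collapse epoch (time units).
#'   Default: the mean-field limit-cycle period when one exists, else 10.
#' @param collapse_threshold Occupancy fraction above which a node is
#'   considered to hold the bulk of the particles (default 0.9).
#' @param empty_threshold Occupancy fraction below which a node is
#'   considered empty (default 0.05).
#' @param burn_in Fraction of the trajectory discarded as transient
#'   (default 0.2).
#' @return An object of class `regime_label`: list with `label` and
#'   `evidence` (the diagnostic scores the decision used).
#' @export
classify_regime <- function(traj, params = NULL, window = NULL,
                            collapse_threshold = 0.9, empty_threshold = 0.05,
                            burn_in = 0.2) {
  stopifnot(inherits(traj, "bdm_trajectory"))
  mk <- function(label, evidence = list())
    structure(list(label = label, evidence = evidence,
                   thresholds = list(collapse = collapse_threshold,
                                     empty = empty_threshold)),
              class = "regime_label")
  if (identical(traj$status, "extinct"))
    return(mk("extinct", list(extinction_time = traj$extinction_time)))
  if (is.null(params)) params <- traj$params
  fr <- occupancy_fractions(traj)
  times <- traj$times[seq_len(nrow(fr))]
  span <- times[length(times)] - times[1L]
  sel <- times >= times[1L] + burn_in * span
  fr <- fr[sel, , drop = FALSE]
  times <- times[sel]
  span <- times[length(times)] - times[1L]
  if (is.null(window)) {
    window <- 10
    if (inherits(params, "bdm_params") && params$N == 3L && params$rho != 0) {
      wc <- tryCatch(limit_cycle(params), error = function(e) NULL)
      if (!is.null(wc) && isTRUE(wc$exists)) window <- wc$period
    }
  }
  if (span < 2 * window || nrow(fr) < 10L)
    return(mk("undetermined", list(reason = "trajectory shorter than two reference periods")))
  N <- ncol(fr)
  dt <- stats::median(diff(times))
  maxfrac <- apply(fr, 1L, max)
  minfrac <- apply(fr, 1L, min)
  leads <- .lead_sequence(fr)
  rot <- .rotation_position(leads, N)
  revolutions <- abs(rot$net) / N
  # completion time of each full revolution
  rot_times <- numeric(0)
  if (!is.null(rot$pos)) {
    for (k in seq_len(floor(max(abs(rot$pos), 0) / N))) {
      i <- which(abs(rot$pos) >= N * k)[1L]
      if (!is.na(i)) rot_times <- c(rot_times, times[rot$change_idx[i]])
    }
  }
  # node-emptying events: distinct dips of the minimum fraction
  empty_runs <- rle(minfrac < empty_threshold)
  empty_events <- sum(empty_runs$values)
  # collapse runs: maximum fraction persistently above the threshold
  cr <- rle(maxfrac > collapse_threshold)
  ends <- cumsum(cr$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  coll <- which(cr$values)
  coll_runs <- data.frame(start = times[starts[coll]], end = times[ends[coll]])
  coll_runs$duration <- coll_runs$end - coll_runs$start + dt
  epochs <- sum(coll_runs$duration >= window)
  coll_frac <- mean(maxfrac > collapse_threshold)
  mid <- times[1L] + span / 2
  coll_frac_2nd <- mean(maxfrac[times >= mid] > collapse_threshold)
  wave_evidence <- revolutions >= 2 && empty_events >= 2
  ev <- list(revolutions = revolutions, empty_events = empty_events,
             collapse_epochs = epochs, collapse_fraction = coll_frac,
             collapse_fraction_second_half = coll_frac_2nd,
             mean_max_fraction = mean(maxfrac), reference_period = window,
             last_rotation_time = if (length(rot_times)) max(rot_times) else NA_real_,
             collapse_runs = coll_runs)
  label <- if (wave_evidence) {
    if (epochs == 0L) "wave"
    else {
      final_idx <- which(coll_runs$end >= times[length(times)] - 2 * dt)
      terminal <- length(final_idx) > 0 &&
        coll_runs$duration[final_idx[1L]] >= 0.5 * span &&
        (length(rot_times) == 0 ||
           max(rot_times) <= coll_runs$start[final_idx[1L]])
      if (terminal) "collapsed" else "intermittent"
    }
  } else {
    if (coll_frac_2nd > 0.9) "collapsed"
    else if (epochs > 0L && revolutions >= 1 && empty_events >= 2) "intermittent"
    else if (epochs == 0L && mean(maxfrac) < 0.55) "amorphous"
    else "undetermined"
  }
  mk(label, ev)
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s\n", x$label))
  if (!is.null(x$evidence$revolutions))
    cat(sprintf("  revolutions %.1f; emptying events %d; collapse epochs %d (fraction %.2f); mean max fraction %.3f\n",
                x$evidence$revolutions, x$evidence$empty_events,
                x$evidence$collapse_epochs, x$evidence$collapse_fraction,
                x$evidence$mean_max_fraction))
  invisible(x)
}

#' Wave frequency of a stochastic trajectory
#'
#' Counts full revolutions of the coherent disturbance — the leading-node
#' label cycling forward (or backward) through all `N` nodes — over the
#' post-burn-in span, and reports revolutions per unit time.  This matches
#' the full-revolution period convention of [limit_cycle()].  The spread is
#' the standard deviation of per-window estimates.
#'
#' @param traj A `bdm_trajectory`.
#' @param window Unused directly; the span is split into `n_windows` pieces.
#' @param n_windows Number of sub-windows used for the spread (default 5).
#' @param burn_in Fraction of the trajectory discarded as transient.
#' @param min_revolutions Signal "no coherent oscillation" (an error of class
#'   `"loopwave_no_oscillation"`) when fewer net revolutions are observed.
#' @return A list with `frequency`, `sd`, `revolutions`, `elapsed`,
#'   `per_window`.
#' @export
estimate_frequency <- function(traj, window = NULL, n_windows = 5L,
                               burn_in = 0.1, min_revolutions = 2) {
  stopifnot(inherits(traj, "bdm_trajectory"))
  fr <- occupancy_fractions(traj)
  times <- traj$times[seq_len(nrow(fr))]
  span <- times[length(times)] - times[1L]
  sel <- times >= times[1L] + burn_in * span
  fr <- fr[sel, , drop = FALSE]; times <- times[sel]
  N <- ncol(fr)
  leads <- .lead_sequence(fr)
  elapsed <- times[length(times)] - times[1L]
  rotpos <- .rotation_position(leads, N)
  revs <- abs(rotpos$net) / N
  # a wave advances the leading node almost exclusively in one direction;
  # undirected flicker in the amorphous state has low coherence even when
  # the weak migration bias gives it a net drift
  if (revs < min_revolutions || rotpos$coherence < 0.5)
    stop(errorCondition(
      sprintf("no coherent oscillation detected (%.1f net revolutions, coherence %.2f)",
              revs, rotpos$coherence),
      class = c("loopwave_no_oscillation", "error", "condition")))
  f_mean <- revs / elapsed
  edges <- seq(times[1L], times[length(times)], length.out = n_windows + 1L)
  per_win <- vapply(seq_len(n_windows), function(k) {
    idx <- times >= edges[k] & times <= edges[k + 1L]
    abs(.rotation_position(leads[idx], N)$net) / N / (edges[k + 1L] - edges[k])
  }, numeric(1))
  list(frequency = f_mean, sd = stats::sd(per_win), revolutions = revs,
       elapsed = elapsed, per_window = per_win)
}

#' Wave amplitude of a stochastic trajectory
#'
#' The amplitude convention is the cycle maximum of the population at node 1
#' divided by the mean per-node population `n_bar/3`, shared with
#' [limit_cycle()]: `A = 1` for a uniform trajectory and `A = 3` when all
#' particles sit at one node.  Cycles are segmented between successive full
#' revolutions of the leading-node label; without at least two full cycles
#' the whole (post-burn-in) window is used as a single segment and the
#' spread is `NA`.
#'
#' @inheritParams estimate_frequency
#' @return A list with `amplitude`, `sd`, `n_cycles`, `per_cycle`.
#' @export
estimate_amplitude <- function(traj, window = NULL, burn_in = 0.1) {
  stopifnot(inherits(traj, "bdm_trajectory"))
  fr <- occupancy_fractions(traj)
  keep <- seq_len(nrow(fr))
  states <- traj$states[keep, , drop = FALSE]
  times <- traj$times[keep]
  span <- times[length(times)] - times[1L]
  sel <- times >= times[1L] + burn_in * span
  states <- states[sel, , drop = FALSE]
  fr <- fr[sel, , drop = FALSE]
  N <- ncol(states)
  leads <- .lead_sequence(fr)
  rot <- .rotation_position(leads, N)
  amp_of <- function(idx) {
    tot <- rowSums(states[idx, , drop = FALSE])
    max(states[idx, 1L]) / (mean(tot) / N)
  }
  cuts <- integer(0)
  if (!is.null(rot$pos)) { # sample index at which each full revolution closes
    target <- N * seq_len(floor(max(abs(rot$pos), 0) / N))
    for (m in target) {
      i <- which(abs(rot$pos) >= m)[1L]
      if (!is.na(i)) cuts <- c(cuts, rot$change_idx[i])
    }
  }
  if (length(cuts) >= 3L) {
    per_cycle <- vapply(seq_len(length(cuts) - 1L), function(k)
      amp_of(cuts[k]:cuts[k + 1L]), numeric(1))
    list(amplitude = mean(per_cycle), sd = stats::sd(per_cycle),
         n_cycles = length(per_cycle), per_cycle = per_cycle)
  } else {
    list(amplitude = amp_of(seq_len(nrow(states))), sd = NA_real_,
         n_cycles = 0L, per_cycle = numeric(0))
  }
}
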