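# Deterministic (macroscopic) dynamics of the three-node loop.
#
# Conventions used throughout this file:
#  * row-vector convention, d<n>/dt = <n> %*% B;
#  * the simplex sum(m) = nbar is conserved exactly along every trajectory;
#  * on the boundary where node e is empty, the "lead" node is the cyclically
#    previous node (for forward bias rho > 0): it fills while the node after
#    e drains.  A negative bias mirrors the loop, handled by reversing node
#    order, so all internal computations assume rho > 0.

.nxt3 <- function(i) i %% 3L + 1L
.prv3 <- function(i) (i - 2L) %% 3L + 1L

#' Interior mean-field flow
#'
#' Rate of change of the mean populations while all nodes are populated:
#' `dm/dt = m %*% B_interior`.  Components sum to zero (conserved mean
#' total); the uniform point `(nbar/3, nbar/3, nbar/3)` is the equilibrium.
#'
#' @param m Numeric vector of mean populations (all positive).
#' @param params A [model_params()] object (`N = 3` for the boundary
#'   analysis; the interior flow itself works for any `N`).
#' @return Numeric vector `dm/dt`.
#' @export
interior_flow <- function(m, params) {
  stopifnot(inherits(params, "bdm_params"), length(m) == params$N)
  as.numeric(m %*% interior_generator(params))
}

#' Blend weight on the simplex boundary
#'
#' On the boundary where node `empty_node` is empty, the mean dynamics is a
#' weighted sum of the interior flow (weight `w = Pr{n_empty > 0}`) and the
#' boundary flow (weight `1 - w`), chosen so that the empty component stays
#' at zero.  Solving that condition gives
#' `w = (3r / 2mu) * (2*rho*x1 + 1 - rho)` with `x1` the population fraction
#' at the lead node.  Sliding along the boundary requires `0 <= w <= 1`,
#' which holds exactly when `x1 <= kappa_b(theta)`.
#'
#' @param m Mean populations with `m[empty_node] = 0`.
#' @inheritParams interior_flow
#' @param empty_node Index of the empty node.
#' @return The weight `w`.
#' @export
boundary_weight <- function(m, params, empty_node) {
  stopifnot(inherits(params, "bdm_params"), params$N == 3L,
            length(m) == 3L, empty_node %in% 1:3)
  if (params$mu == 0)
    stop("boundary weight undefined for mu = 0", call. = FALSE)
  nbar <- sum(m)
  stopifnot(abs(m[empty_node]) <= 1e-9 * nbar)
  lead <- if (params$rho >= 0) .prv3(empty_node) else .nxt3(empty_node)
  x1 <- m[lead] / nbar
  (3 * params$r / (2 * params$mu)) * (2 * abs(params$rho) * x1 + 1 - abs(params$rho))
}

#' Sliding flow along a simplex boundary
#'
#' Evolution of the mean state while pinned to the boundary with node
#' `empty_node` empty: the lead-node fraction `x1 = m_lead / nbar` obeys
#' `dx1/dt = (r*|rho|*theta / 2) * (x1 - kappa_e(theta))`, the other
#' populated node changes oppositely, and the empty component is held at
#' exactly zero.  Valid only while the sliding condition `0 <= w <= 1`
#' holds; outside it an error of class `"loopwave_exit_boundary"` is
#' signalled and the caller must switch to [interior_flow()].
#'
#' @inheritParams boundary_weight
#' @return Numeric vector `dm/dt` with a zero in position `empty_node`.
#' @export
boundary_flow <- function(m, params, empty_node) {
  w <- boundary_weight(m, params, empty_node)
  if (w < -1e-12 || w > 1 + 1e-12)
    stop(errorCondition(
      sprintf("sliding condition violated (w = %.6f): trajectory exits the boundary", w),
      class = c("loopwave_exit_boundary", "error", "condition")))
  theta <- abs(control_parameter(params))
  nbar <- sum(m)
  lead <- if (params$rho >= 0) .prv3(empty_node) else .nxt3(empty_node)
  other <- if (params$rho >= 0) .nxt3(empty_node) else .prv3(empty_node)
  x1 <- m[lead] / nbar
  dx1 <- (params$r * abs(params$rho) * theta / 2) *
    (x1 - if (theta != 0) kappa_e(theta) else 0)
  dm <- numeric(3)
  dm[lead] <- dx1 * nbar
  dm[other] <- -dx1 * nbar
  dm
}

# Eigen-decomposition of the interior generator, cached per call site.
.interior_propagator <- function(params) {
  B <- interior_generator(params)
  e <- eigen(B)
  list(V = e$vectors, Vinv = solve(e$vectors), lambda = e$values, B = B,
       omega = (sqrt(3) / 2) * params$r * abs(params$rho),
       growth = params$mu - 1.5 * params$r)
}

# Closed-form interior solution m(t) = m0 expm(B t), vectorized over times.
.interior_states <- function(prop, m0, ts) {
  coef <- as.complex(m0) %*% prop$V
  E <- exp(outer(ts, prop$lambda))
  Re((E * matrix(coef, nrow = length(ts), ncol = length(coef), byrow = TRUE)) %*%
       prop$Vinv)
}

#' Closed-form interior solution
#'
#' Exact solution of the linear interior mean-field system from `m0`,
#' evaluated by eigendecomposition of the generator (the trajectory is an
#' exponential spiral about the centre with growth rate `mu - 3r/2` and
#' angular frequency `sqrt(3) r |rho| / 2`).
#'
#' @inheritParams interior_flow
#' @param m0 Initial mean populations.
#' @param times Numeric vector of times.
#' @return A matrix with one row per time, columns `m_1..m_N`.
#' @export
meanfield_interior_solution <- function(params, m0, times) {
  stopifnot(inherits(params, "bdm_params"), length(m0) == params$N)
  prop <- .interior_propagator(params)
  M <- .interior_states(prop, m0, times)
  colnames(M) <- paste0("m_", seq_len(params$N))
  M
}

# First time a simplex component reaches zero along the interior flow.
# Components starting at (numerical) zero are ignored until they have grown
# past arm_eps, so a freshly departed boundary node cannot retrigger.
# Returns NULL if no component reaches zero within t_limit.
.interior_hit <- function(prop, m0, t_limit, nbar) {
  if (t_limit <= 0) return(NULL)
  arm_eps <- 1e-7 * nbar
  T_rot <- if (prop$omega > 0) 2 * pi / prop$omega else 2 / max(abs(prop$growth), 1e-6)
  dt <- T_rot / 256
  ts <- seq(dt, t_limit, by = dt)
  if (length(ts) == 0) ts <- t_limit
  M <- .interior_states(prop, m0, ts)
  best_t <- Inf; best_j <- NA_integer_
  for (j in seq_along(m0)) {
    col <- M[, j]
    if (m0[j] > arm_eps) {
      i_arm <- 1L
    } else {
      above <- which(col > arm_eps)
      if (length(above) == 0) next
      i_arm <- above[1L]
    }
    idx <- which(col[i_arm:length(col)] <= 0)
    if (length(idx) == 0) next
    i_hit <- i_arm + idx[1L] - 1L
    t_lo <- if (i_hit > 1L) ts[i_hit - 1L] else 0
    t_hi <- ts[i_hit]
    f <- function(t) .interior_states(prop, m0, t)[1L, j]
    if (f(t_lo) <= 0) { t_cross <- t_lo } else {
      t_cross <- stats::uniroot(f, c(t_lo, t_hi), tol = 1e-12)$root
    }
    if (t_cross < best_t) { best_t <- t_cross; best_j <- j }
  }
  if (!is.finite(best_t)) return(NULL)
  m <- as.numeric(.interior_states(prop, m0, best_t))
  m[best_j] <- 0
  m[m < 0] <- 0
  m <- m * nbar / sum(m)
  list(t = best_t, m = m, node = best_j)
}

#' Critical control parameter of the wave state
#'
#' The value `theta_c` above which the deterministic limit cycle cannot
#' exist, obtained as the root of the transcendental condition
#' `l(theta_c / sqrt(3)) + pi/6 = 0` with `l(x) = log(x)/x`, bracketed in
#' `(1, sqrt(3))`.  At `theta_c` the cycle grazes each boundary exactly at
#' the unstable boundary equilibrium `kappa_e`.
#'
#' @param tol Root-finding tolerance.
#' @return The critical value, approximately 1.2037.
#' @examples
#' theta_critical()
#' @export
theta_critical <- function(tol = 1e-12) {
  l <- function(x) log(x) / x
  stats::uniroot(function(th) l(th / sqrt(3)) + pi / 6,
                 interval = c(1, sqrt(3)), tol = tol)$root
}

# Departure-to-arrival map of the hybrid flow, in population fractions
# (nbar = 1), for forward bias.  Departing from the boundary with node 2
# empty at the exit point (kappa_b, 0, 1 - kappa_b), the interior spiral is
# followed until the next component empties (node 3 on the cycle); returns
# the interior transit time and the arrival fraction at the new lead node.
.cycle_segment <- function(params, theta, prop = .interior_propagator(params)) {
  kb <- kappa_b(theta)
  m0 <- c(kb, 0, 1 - kb)
  T_rot <- 2 * pi / prop$omega
  hit <- .interior_hit(prop, m0, t_limit = 50 * T_rot, nbar = 1)
  if (is.null(hit)) return(NULL)
  lead_new <- .prv3(hit$node)
  list(t_int = hit$t, node = hit$node, x_arr = hit$m[lead_new], m_arr = hit$m,
       m0 = m0)
}

#' Limit cycle of the wave state
#'
#' Locates the attracting hybrid limit cycle for `0 < theta < theta_c` via
#' its Poincare section (the exit point `kappa_b` on a boundary), and
#' returns the wave characteristics: the period is three boundary-to-boundary
#' segments by cyclic symmetry, the frequency counts full revolutions of the
#' disturbance (`f = 1/period`, with the scaled form
#' `fhat = f / (r |rho|)` depending on `theta` alone), and the amplitude is
#' the cycle maximum of one node's population divided by the mean per-node
#' population `nbar/3` (so `A = 1` at the uniform state and `A -> 3` at full
#' collapse).  A negative bias gives the mirror-image cycle with identical
#' frequency and amplitude.
#'
#' @inheritParams interior_flow
#' @param n_cycle_samples Samples per segment used for the amplitude maximum
#'   (refined afterwards by local optimization).
#' @return An object of class `wave_characteristics`: `theta` (signed),
#'   `frequency`, `fhat`, `amplitude`, `period`, `exists`, `marginal`, plus
#'   a `details` list (`t_interior`, `t_slide`, `x_arrival`, `kappa_b`,
#'   `kappa_e`).
#' @export
limit_cycle <- function(params, n_cycle_samples = 2000L) {
  stopifnot(inherits(params, "bdm_params"))
  if (params$N != 3L)
    stop("limit-cycle analysis is defined for the three-node loop", call. = FALSE)
  if (params$rho == 0)
    stop("undefined control parameter: rho = 0 (no oscillatory regime exists)",
         call. = FALSE)
  theta_signed <- control_parameter(params)
  pa <- model_params(params$r, abs(params$rho), params$mu, 3L)
  theta <- control_parameter(pa)
  out <- function(exists, marginal = FALSE, f = NA_real_, fhat = NA_real_,
                  A = NA_real_, period = NA_real_, details = list())
    structure(list(theta = theta_signed, frequency = f, fhat = fhat,
                   amplitude = A, period = period, exists = exists,
                   marginal = marginal, details = details, params = params),
              class = "wave_characteristics")
  thc <- theta_critical()
  if (theta <= 0)
    return(out(FALSE, marginal = (theta == 0)))
  if (theta >= thc)
    return(out(FALSE, marginal = (abs(theta - thc) < 1e-10)))
  kb <- kappa_b(theta); ke <- kappa_e(theta)
  prop <- .interior_propagator(pa)
  seg1 <- .cycle_segment(pa, theta, prop)
  seg2 <- .cycle_segment(pa, theta, prop) # Poincare map is idempotent here:
  # the slide resets every departure to kappa_b, so successive crossings
  # must agree; assert it rather than assume it.
  if (is.null(seg1) || is.null(seg2))
    return(out(FALSE, details = list(reason = "no boundary return")))
  stopifnot(abs(seg1$x_arr - seg2$x_arr) <= 1e-9, seg1$node == seg2$node)
  if (seg1$node != 3L)
    return(out(FALSE, details = list(reason = "unexpected cycle geometry")))
  if (seg1$x_arr <= ke)
    return(out(FALSE, details = list(x_arrival = seg1$x_arr, kappa_e = ke)))
  g <- pa$r * pa$rho * theta / 2
  t_slide <- log((kb - ke) / (seg1$x_arr - ke)) / g
  period <- 3 * (seg1$t_int + t_slide)
  f <- 1 / period
  fhat <- f / (pa$r * pa$rho)
  # amplitude: by cyclic symmetry the cycle maximum of a fixed node equals
  # the maximum over all components of one interior segment (the slide
  # maximum is kappa_b, reached at departure).
  ts <- seq(0, seg1$t_int, length.out = n_cycle_samples)
  Mseg <- .interior_states(prop, seg1$m0, ts)
  i_max <- which(Mseg == max(Mseg), arr.ind = TRUE)[1L, ]
  j <- i_max[2L]
  lo <- ts[max(1L, i_max[1L] - 1L)]; hi <- ts[min(length(ts), i_max[1L] + 1L)]
  peak <- if (hi > lo)
    stats::optimize(function(t) .interior_states(prop, seg1$m0, t)[1L, j],
                    c(lo, hi), maximum = TRUE)$objective
  else max(Mseg)
  amp_frac <- max(peak, kb)
  out(TRUE, f = f, fhat = fhat, A = 3 * amp_frac, period = period,
      details = list(t_interior = seg1$t_int, t_slide = t_slide,
                     x_arrival = seg1$x_arr, kappa_b = kb, kappa_e = ke))
}

#' @export
print.wave_characteristics <- function(x, ...) {
  if (x$exists) {
    cat(sprintf("Wave limit cycle at theta = %g:\n", x$theta))
    cat(sprintf("  frequency f = %.6f (fhat = %.6f), period %.4f\n",
                x$frequency, x$fhat, x$period))
    cat(sprintf("  amplitude A = %.4f (max node population / (nbar/3))\n",
                x$amplitude))
  } else {
    cat(sprintf("No limit cycle at theta = %g%s\n", x$theta,
                if (isTRUE(x$marginal)) " (marginal case)" else ""))
  }
  invisible(x)
}

#' Control parameter at which the limit cycle grazes the boundary
#'
#' Continues the hybrid limit cycle in `theta` until its boundary-arrival
#' coordinate meets the unstable boundary equilibrium `kappa_e` — the
#' grazing point beyond which the cycle cannot close.  This provides an
#' independent numerical determination of the critical value returned
#' analytically by [theta_critical()].
#'
#' @param r,rho Migration rate and bias used for the continuation (the
#'   grazing value depends on `theta` only).
#' @param tol Root-finding tolerance in `theta`.
#' @return The grazing `theta`.
#' @export
grazing_theta <- function(r = 1, rho = 1, tol = 1e-10) {
  gap <- function(th) {
    mu <- (th * r * abs(rho) + 3 * r) / 2
    pa <- model_params(r, abs(rho), mu, 3L)
    seg <- .cycle_segment(pa, th)
    seg$x_arr - kappa_e(th)
  }
  stats::uniroot(gap, c(1.05, 1.35), tol = tol)$root
}

#' Hybrid mean-field trajectory
#'
#' Event-driven integration of the piecewise-smooth mean-field system:
#' closed-form spiral flow in the simplex interior, detection of the first
#' boundary contact by bracketed root-finding, then either sliding along the
#' boundary (exact scalar solution) until the exit threshold `kappa_b` is
#' reached, or — when the arrival point lies below the unstable boundary
#' equilibrium `kappa_e` (possible for `theta > 1`) — sliding into the
#' vertex, where the system is trapped in the collapsed state.
#'
#' @inheritParams interior_flow
#' @param m0 Initial mean populations on the simplex (non-negative, positive
#'   sum).
#' @param t_max Integration horizon.
#' @param sample_dt Output sampling interval (default `t_max/2000`).
#' @return An object of class `meanfield_trajectory`: a list with
#'   `trajectory` (data frame `t`, `m_1..m_3`, `region`), `label` (one of
#'   `"amorphous"`, `"limit_cycle"`, `"collapsed"`, `"undetermined"`),
#'   `departures` (number of boundary exits seen), `params`, `nbar`.
#' @export
integrate_meanfield <- function(params, m0, t_max = 200, sample_dt = NULL) {
  stopifnot(inherits(params, "bdm_params"), params$N == 3L,
            length(m0) == 3L, all(m0 >= 0), sum(m0) > 0, t_max > 0)
  if (params$rho == 0)
    stop("boundary dynamics undefined for rho = 0", call. = FALSE)
  if (params$rho < 0) {
    # mirror the loop: reverse node order, flip the bias, map back
    pa <- model_params(params$r, -params$rho, params$mu, 3L)
    res <- integrate_meanfield(pa, rev(m0), t_max, sample_dt)
    tr <- res$trajectory
    tr[, c("m_1", "m_2", "m_3")] <- tr[, c("m_3", "m_2", "m_1")]
    tr$region <- chartr("13", "31", tr$region)
    res$trajectory <- tr
    res$params <- params
    return(res)
  }
  if (is.null(sample_dt)) sample_dt <- t_max / 2000
  nbar <- sum(m0)
  eps_b <- 1e-9 * nbar
  theta <- control_parameter(params)
  thc <- theta_critical()
  kb <- kappa_b(theta)
  ke <- if (theta != 0) kappa_e(theta) else NA_real_
  g <- params$r * params$rho * theta / 2
  prop <- .interior_propagator(params)
  centre <- rep(nbar / 3, 3)

  rows <- list()
  emit <- function(ts, M, region) {
    rows[[length(rows) + 1L]] <<- data.frame(
      t = ts, m_1 = M[, 1], m_2 = M[, 2], m_3 = M[, 3], region = region,
      stringsAsFactors = FALSE)
  }
  slide_states <- function(x0, x1_fun, ts_local, e) {
    lead <- .prv3(e); other <- .nxt3(e)
    x <- x1_fun(ts_local)
    M <- matrix(0, length(ts_local), 3)
    M[, lead] <- x * nbar
    M[, other] <- (1 - x) * nbar
    M
  }

  t <- 0; m <- m0; label <- NULL; departures <- 0L
  region <- if (all(m > eps_b)) "interior" else "boundary"
  e <- if (region == "boundary") which.min(m) else NA_integer_
  guard <- 0L
  while (is.null(label)) {
    guard <- guard + 1L
    if (guard > 100000L) { label <- "undetermined"; break }
    rem <- t_max - t
    if (rem <= 1e-12) {
      label <- if (departures >= 2L) "limit_cycle" else "undetermined"
      break
    }
    if (region == "interior") {
      hit <- .interior_hit(prop, m, rem, nbar)
      dur <- if (is.null(hit)) rem else hit$t
      ts_local <- unique(c(seq(0, dur, by = sample_dt), dur))
      emit(t + ts_local, .interior_states(prop, m, ts_local), "interior")
      if (is.null(hit)) {
        m_end <- as.numeric(.interior_states(prop, m, rem))
        t <- t_max; m <- m_end
        d <- sqrt(sum((m_end - centre)^2))
        label <- if (d < 1e-6 * nbar) "amorphous"
        else if (departures >= 2L) "limit_cycle" else "undetermined"
      } else {
        t <- t + hit$t; m <- hit$m; e <- hit$node; region <- "boundary"
      }
    } else { # boundary with node e empty
      zero <- which(m <= eps_b)
      if (length(zero) >= 2L) { # vertex: absorbing for the mean flow
        m <- replace(numeric(3), which.max(m), nbar)
        label <- "collapsed"
        break
      }
      m[e] <- 0
      lead <- .prv3(e); other <- .nxt3(e)
      x0 <- m[lead] / nbar
      if (theta == 0) { label <- "undetermined"; break } # non-hyperbolic
      if (x0 >= kb - 1e-12) { # beyond the sliding range: leaves at once
        region <- "interior"
        departures <- departures + 1L
        next
      }
      dx <- g * (x0 - ke)
      if (dx > 0) { # slides up to the exit threshold kappa_b
        t_s <- log((kb - ke) / (x0 - ke)) / g
        xfun <- function(s) ke + (x0 - ke) * exp(g * s)
        if (t_s <= rem) {
          ts_local <- unique(c(seq(0, t_s, by = sample_dt), t_s))
          emit(t + ts_local, slide_states(x0, xfun, ts_local, e),
               paste0("boundary_", e))
          t <- t + t_s
          m <- numeric(3); m[lead] <- kb * nbar; m[other] <- (1 - kb) * nbar
          departures <- departures + 1L
          region <- "interior"
        } else {
          ts_local <- unique(c(seq(0, rem, by = sample_dt), rem))
          emit(t + ts_local, slide_states(x0, xfun, ts_local, e),
               paste0("boundary_", e))
          t <- t_max
          label <- if (departures >= 2L) "limit_cycle" else "undetermined"
        }
      } else if (dx < 0) { # slides into the vertex: collapse
        t_v <- log(ke / (ke - x0)) / g
        xfun <- function(s) pmax(ke + (x0 - ke) * exp(g * s), 0)
        dur <- min(t_v, rem)
        ts_local <- unique(c(seq(0, dur, by = sample_dt), dur))
        emit(t + ts_local, slide_states(x0, xfun, ts_local, e),
             paste0("boundary_", e))
        t <- t + dur
        if (t_v <= rem) {
          m <- numeric(3); m[other] <- nbar
          label <- "collapsed"
        } else label <- "undetermined"
      } else { # exactly at the unstable boundary equilibrium
        label <- "undetermined"
      }
    }
  }
  traj <- do.call(rbind, rows)
  if (is.null(traj))
    traj <- data.frame(t = t, m_1 = m[1], m_2 = m[2], m_3 = m[3],
                       region = region, stringsAsFactors = FALSE)
  structure(list(trajectory = traj, label = label, final = m,
                 departures = departures, params = params, nbar = nbar,
                 theta = theta),
            class = "meanfield_trajectory")
}

#' @export
print.meanfield_trajectory <- function(x, ...) {
  cat(sprintf("Mean-field hybrid trajectory (theta = %g): %s after %d boundary exits\n",
              x$theta, x$label, x$departures))
  cat(sprintf("  final state: (%.4f, %.4f, %.4f), nbar = %g\n",
              x$final[1], x$final[2], x$final[3], x$nbar))
  invisible(x)
}

#' Wave frequency and amplitude across the control parameter
#'
#' Evaluates [limit_cycle()] over a grid of `theta` values at fixed `r` and
#' `rho` (the birth-death rate is set to `mu = (theta r |rho| + 3 r)/2` for
#' each point).  The scaled frequency decreases and the amplitude increases
#' with `theta`; no cycle exists beyond `theta_c`.
#'
#' @param params_base A [model_params()] supplying `r` and `rho` (its `mu`
#'   is ignored).
#' @param thetas Numeric grid of control-parameter values.
#' @return A data frame with columns `theta`, `mu`, `fhat`, `frequency`,
#'   `amplitude`, `period`, `exists`, plus attributes `fhat_decreasing` and
#'   `amplitude_increasing` evaluated over the rows where a cycle exists.
#' @export
wave_characteristics_curve <- function(params_base, thetas) {
  stopifnot(inherits(params_base, "bdm_params"), params_base$rho != 0)
  r <- params_base$r; rho <- abs(params_base$rho)
  rows <- lapply(thetas, function(th) {
    mu <- (th * r * rho + 3 * r) / 2
    wc <- limit_cycle(model_params(r, rho, mu, 3L))
    data.frame(theta = th, mu = mu, fhat = wc$fhat, frequency = wc$frequency,
               amplitude = wc$amplitude, period = wc$period, exists = wc$exists)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(theta = numeric(0), mu = numeric(0), fhat = numeric(0),
                      frequency = numeric(0), amplitude = numeric(0),
                      period = numeric(0), exists = logical(0))
  ok <- out$exists
  attr(out, "fhat_decreasing") <-
    sum(ok) < 2 || all(diff(out$fhat[ok]) < 0)
  attr(out, "amplitude_increasing") <-
    sum(ok) < 2 || all(diff(out$amplitude[ok]) > 0)
  out
}
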