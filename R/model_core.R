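#' Parameters of the birth-death-migration loop model
#'
#' Bundles the dynamical rates of the process together with the network size.
#' Particles sit on a directed loop of `N` nodes.  Each particle migrates to a
#' neighbouring node at rate `r`, choosing the forward direction
#' (node `i` to `i + 1`, cyclically) with probability `(1 + rho)/2` and the
#' backward direction with probability `(1 - rho)/2`.  Each particle gives
#' birth at rate `mu`; deaths remove particles at total rate `mu * n_tot`,
#' drawn with equal probability from each *populated* node, so the total
#' population performs a critical birth-death process whose mean is conserved.
#'
#' @param r Migration rate per particle per unit time (`r > 0`).
#' @param rho Directional bias of migration, dimensionless, in `[-1, 1]`.
#'   `rho = 0` means unbiased migration; `|rho| = 1` a pure one-way cycle.
#' @param mu Birth rate per particle, equal to the total death rate per
#'   particle (`mu >= 0`).
#' @param N Number of nodes in the loop (`N >= 2`; the wave analysis requires
#'   `N >= 3`).
#'
#' @return An object of class `bdm_params`.
#' @examples
#' model_params(r = 1, rho = 1, mu = 1.8)
#' @export
model_params <- function(r, rho, mu, N = 3L) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
            is.numeric(rho), length(rho) == 1L, rho >= -1, rho <= 1,
            is.numeric(mu), length(mu) == 1L, is.finite(mu), mu >= 0,
            is.numeric(N), length(N) == 1L, N >= 2, N == round(N))
  structure(list(r = r, rho = rho, mu = mu, N = as.integer(N)),
            class = "bdm_params")
}

#' @export
print.bdm_params <- function(x, ...) {
  cat(sprintf("Birth-death-migration loop model (N = %d nodes)\n", x$N))
  cat(sprintf("  migration rate r   = %g\n", x$r))
  cat(sprintf("  directional bias   = %g\n", x$rho))
  cat(sprintf("  birth/death rate   = %g\n", x$mu))
  if (x$rho != 0 && x$N == 3L)
    cat(sprintf("  control parameter  = %g\n", control_parameter(x)))
  invisible(x)
}

#' System state: integer populations on the loop
#'
#' @param n Vector of `N` non-negative integer populations.
#' @param t Time attached to the state.
#' @return An object of class `bdm_state` with fields `n` and `t`.  The number
#'   of populated nodes `Z` is always recomputed with [populated_nodes()],
#'   never stored.
#' @export
system_state <- function(n, t = 0) {
  stopifnot(is.numeric(n), length(n) >= 2L, all(is.finite(n)),
            all(n >= 0), all(n == round(n)),
            is.numeric(t), length(t) == 1L, t >= 0)
  structure(list(n = as.numeric(n), t = t), class = "bdm_state")
}

#' Number of populated nodes of a state
#'
#' @param state A [system_state()] or a bare population vector.
#' @return Integer count of nodes with at least one particle.
#' @export
populated_nodes <- function(state) {
  n <- if (inherits(state, "bdm_state")) state$n else state
  sum(n > 0)
}

#' Migration rate matrix of the loop
#'
#' Row-vector convention throughout: mean populations evolve as
#' `d<n>/dt = <n> %*% B`, so row `i` of a generator holds the rates *out of*
#' node `i`.  Row `i` of `M` has `-r` on the diagonal, `r(1 + rho)/2` in the
#' forward column `i + 1` (mod `N`) and `r(1 - rho)/2` in the backward column
#' `i - 1` (mod `N`).  Rows sum to zero: migration conserves particles.
#'
#' @param params A [model_params()] object.
#' @return An `N x N` numeric matrix.
#' @examples
#' migration_matrix(model_params(1, 1, 0))
#' @export
migration_matrix <- function(params) {
  stopifnot(inherits(params, "bdm_params"))
  N <- params$N
  M <- matrix(0, N, N)
  fwd <- params$r * (1 + params$rho) / 2
  bwd <- params$r * (1 - params$rho) / 2
  for (i in seq_len(N)) {
    M[i, i] <- M[i, i] - params$r
    jf <- i %% N + 1L
    jb <- (i - 2L) %% N + 1L
    M[i, jf] <- M[i, jf] + fwd
    M[i, jb] <- M[i, jb] + bwd
  }
  M
}

#' Interior mean-field generator
#'
#' Generator of the deterministic mean dynamics while every node is populated:
#' `B = M + mu * I - (mu/N) * U`, where `I` is the identity (births) and `U`
#' the all-ones matrix (the global death process spread over all `N` nodes).
#' The uniform vector is a left eigenvector with eigenvalue 0 (the conserved
#' mean total).
#'
#' @inheritParams migration_matrix
#' @return An `N x N` numeric matrix, rows summing to zero.
#' @export
interior_generator <- function(params) {
  stopifnot(inherits(params, "bdm_params"))
  N <- params$N
  migration_matrix(params) + params$mu * diag(N) -
    (params$mu / N) * matrix(1, N, N)
}

#' Boundary mean-field generator (one node empty)
#'
#' Generator of the mean dynamics conditional on node `empty_node` being
#' empty: `B = M + mu * I - (mu/2) * U2`, where `U2` is the all-ones matrix
#' with column `empty_node` zeroed — deaths are shared between the two
#' populated nodes only.  Derived for the three-node loop; larger loops are
#' refused rather than guessed.
#'
#' @inheritParams migration_matrix
#' @param empty_node Index (1..3) of the depleted node.
#' @return A `3 x 3` numeric matrix, rows summing to zero.
#' @export
boundary_generator <- function(params, empty_node) {
  stopifnot(inherits(params, "bdm_params"))
  if (params$N != 3L)
    stop("boundary analysis unsupported for N != 3", call. = FALSE)
  stopifnot(empty_node %in% 1:3)
  U2 <- matrix(1, 3, 3)
  U2[, empty_node] <- 0
  migration_matrix(params) + params$mu * diag(3) - (params$mu / 2) * U2
}

#' Control parameter of the three-node loop
#'
#' The single combination `theta = (2*mu - 3*r) / (r*rho)` that governs the
#' wave and collapse transitions of the three-node loop.  `theta <= 0` gives
#' the amorphous state, `0 < theta < theta_c` supports the wave state and
#' `theta > theta_c` forces collapse (see [theta_critical()]).
#'
#' @inheritParams migration_matrix
#' @return A single number.
#' @examples
#' control_parameter(model_params(1, 1, 1.8)) # 0.6, the wave regime
#' @export
control_parameter <- function(params) {
  stopifnot(inherits(params, "bdm_params"))
  if (params$rho == 0)
    stop("undefined control parameter: rho = 0 (no oscillatory regime exists)",
         call. = FALSE)
  (2 * params$mu - 3 * params$r) / (params$r * params$rho)
}

#' Eigenvalues of the interior mean-field generator
#'
#' Closed-form spectrum of the loop generator: `sigma_0 = 0` for the conserved
#' mean total, and for `k = 1, ..., N-1`
#' `sigma_k = mu - r + r*cos(2*pi*k/N) + i*r*rho*sin(2*pi*k/N)`,
#' which come in complex-conjugate pairs.  At `N = 3` the nonzero pair is
#' `mu - (3/2) r +/- i (sqrt(3)/2) r rho`.  A nonzero imaginary part (needing
#' `N >= 3` and `rho != 0`) is what permits rotating-wave solutions.
#'
#' @inheritParams migration_matrix
#' @return An object of class `bdm_spectrum`: a list with `eigenvalues`
#'   (complex vector, `sigma_0` first), `hopf_threshold` (critical `mu`, `NA`
#'   for `N = 2`) and `is_oscillatory`.
#' @export
interior_eigenvalues <- function(params) {
  stopifnot(inherits(params, "bdm_params"))
  N <- params$N
  k <- seq_len(N) - 1L
  sigma <- complex(real = params$mu - params$r + params$r * cos(2 * pi * k / N),
                   imaginary = params$r * params$rho * sin(2 * pi * k / N))
  sigma[1L] <- 0 + 0i
  structure(list(eigenvalues = sigma,
                 hopf_threshold = if (N >= 3L) hopf_threshold(params) else NA_real_,
                 is_oscillatory = any(abs(Im(sigma)) > 0),
                 params = params),
            class = "bdm_spectrum")
}

#' @export
print.bdm_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum of the interior generator (N = %d)\n", x$params$N))
  for (s in x$eigenvalues)
    cat(sprintf("  %+.6f %+.6fi\n", Re(s), Im(s)))
  cat(sprintf("  Hopf threshold mu* = %s\n", format(x$hopf_threshold)))
  cat(sprintf("  oscillatory: %s\n", x$is_oscillatory))
  invisible(x)
}

#' Critical birth-death rate of the amorphous state
#'
#' The uniform equilibrium loses stability when the leading conjugate
#' eigenvalue pair (`k = 1, N-1`) crosses the imaginary axis, at
#' `mu = r * (1 - cos(2*pi/N))` — independent of the bias `rho`.  For `N = 3`
#' this is the Hopf point `mu = (3/2) r`; the threshold decreases to zero as
#' the loop grows.
#'
#' @inheritParams migration_matrix
#' @return The critical `mu`, a single number.
#' @examples
#' hopf_threshold(model_params(1, 1, 0, N = 10)) # ~0.19
#' @export
hopf_threshold <- function(params) {
  stopifnot(inherits(params, "bdm_params"))
  if (params$N < 3L)
    stop("Hopf threshold requires N >= 3", call. = FALSE)
  params$r * (1 - cos(2 * pi / params$N))
}

#' Boundary thresholds kappa_b and kappa_e
#'
#' On a boundary of the mean-field simplex (one node empty), the fraction
#' `x = <n_lead>/n_bar` held by the growing node determines the motion.
#' `kappa_b(theta) = (1 + theta/3)/2` is the largest `x` at which the sliding
#' condition (blend weight `w <= 1`) can hold: the trajectory leaves the
#' boundary when `x` exceeds it.  `kappa_e(theta) = (1 - 1/theta)/2` is the
#' unstable equilibrium on the boundary separating wave-bound from
#' collapse-bound sliding.
#'
#' @param theta Control parameter value (see [control_parameter()]).
#' @return A single number.
#' @export
kappa_b <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  (1 + theta / 3) / 2
}

#' @rdname kappa_b
#' @export
kappa_e <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  if (theta == 0)
    stop("kappa_e undefined at theta = 0", call. = FALSE)
  (1 - 1 / theta) / 2
}

#' Predicted regime from the deterministic analysis
#'
#' Maps parameters to the regime the mean-field analysis predicts for generic
#' initial conditions: amorphous for `theta <= 0`, wave for
#' `0 < theta < 1`, bistable wave/collapse (seen as intermittency in
#' stochastic runs) for `1 < theta < theta_c`, collapsed beyond `theta_c`.
#' For `rho = 0` no oscillation is possible and the system is amorphous below
#' the stability threshold, collapsed above it.  `theta` is computed with the
#' signed `rho`; the regime depends on its magnitude (a negative bias mirrors
#' the wave direction).
#'
#' @inheritParams migration_matrix
#' @return A character label.
#' @export
predict_regime <- function(params) {
  stopifnot(inherits(params, "bdm_params"))
  if (params$rho == 0) {
    thr <- if (params$N >= 3L) hopf_threshold(params) else params$r * 2
    return(if (params$mu < thr) "amorphous" else "collapsed")
  }
  th <- abs(control_parameter(params))
  unstable <- 2 * params$mu - 3 * params$r > 0
  if (!unstable) return("amorphous")
  thc <- theta_critical()
  if (th < 1) "wave" else if (th < thc) "intermittent" else "collapsed"
}
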