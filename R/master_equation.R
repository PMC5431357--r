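#' Enumerate the truncated population lattice
#'
#' Builds a bijection between the non-negative integer configurations
#' `(n_1, ..., n_N)` with total population at most `n_max` and the indices
#' `1..K`, where `K = choose(n_max + N, N)`.  States are ordered by total
#' population, then lexicographically, which keeps the single-particle sector
#' in a contiguous block.
#'
#' @param N Number of nodes.
#' @param n_max Truncation: largest total population enumerated (>= 0).
#' @return An object of class `state_space`: list with `N`, `n_max`, `states`
#'   (a `K x N` integer matrix, one state per row) and `lookup` (named index
#'   vector keyed by `paste(state, collapse = ",")`).
#' @examples
#' enumerate_states(3, 2) # 10 states
#' @export
enumerate_states <- function(N, n_max) {
  stopifnot(N >= 1, n_max >= 0, (n_max + 1)^N <= 5e6)
  grid <- as.matrix(do.call(expand.grid, rep(list(0:n_max), N)))
  grid <- grid[, rev(seq_len(N)), drop = FALSE] # column j is n_j
  keep <- rowSums(grid) <= n_max
  sts <- grid[keep, , drop = FALSE]
  ord <- do.call(order, c(list(rowSums(sts)),
                          lapply(seq_len(N), function(j) sts[, j])))
  sts <- sts[ord, , drop = FALSE]
  dimnames(sts) <- list(NULL, paste0("n_", seq_len(N)))
  key <- apply(sts, 1L, paste, collapse = ",")
  structure(list(N = as.integer(N), n_max = as.integer(n_max),
                 states = sts,
                 lookup = stats::setNames(seq_along(key), key)),
            class = "state_space")
}

#' @rdname enumerate_states
#' @param space A `state_space`.
#' @param state A population vector.
#' @return `state_index()` returns the integer index of `state` (or `NA` if
#'   it lies outside the truncation).
#' @export
state_index <- function(space, state) {
  stopifnot(inherits(space, "state_space"))
  idx <- space$lookup[paste(as.integer(state), collapse = ",")]
  unname(idx)
}

#' Truncated master-equation generator
#'
#' Assembles the sparse transition-rate matrix `A` of the process on the
#' truncated lattice, with the column convention `dP/dt = A %*% P` (entry
#' `A[target, source]` is the rate of the jump `source -> target`; the
#' diagonal is minus the total outflow rate of the source state, *including*
#' birth jumps that would leave the truncation).  Those suppressed births are
#' reported per state in `leak_rate`, so retained probability mass decays at
#' exactly the leakage rate — the truncation error is tracked, never hidden.
#' Off-diagonal rates are exactly the [propensities()] of the simulator.
#'
#' @param params A [model_params()] object.
#' @param n_max Truncation of the total population (>= 1).
#' @return An object of class `bdm_generator`: list with sparse `A`
#'   (`K x K`, `Matrix::dgCMatrix`), `leak_rate` (length `K`) and `space`.
#' @export
build_generator <- function(params, n_max) {
  stopifnot(inherits(params, "bdm_params"), n_max >= 1)
  space <- enumerate_states(params$N, n_max)
  K <- nrow(space$states)
  N <- params$N
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_out <- numeric(K)
  leak <- numeric(K)
  add <- function(tgt_state) state_index(space, tgt_state)
  for (s in seq_len(K)) {
    n <- space$states[s, ]
    p <- propensities(n, params)
    for (i in seq_len(N)) {
      if (p$forward[i] > 0) {
        tgt <- n; tgt[i] <- tgt[i] - 1L
        k2 <- i %% N + 1L; tgt[k2] <- tgt[k2] + 1L
        ii <- c(ii, add(tgt)); jj <- c(jj, s); xx <- c(xx, p$forward[i])
        diag_out[s] <- diag_out[s] + p$forward[i]
      }
      if (p$backward[i] > 0) {
        tgt <- n; tgt[i] <- tgt[i] - 1L
        k2 <- (i - 2L) %% N + 1L; tgt[k2] <- tgt[k2] + 1L
        ii <- c(ii, add(tgt)); jj <- c(jj, s); xx <- c(xx, p$backward[i])
        diag_out[s] <- diag_out[s] + p$backward[i]
      }
      if (p$birth[i] > 0) {
        if (sum(n) + 1L <= n_max) {
          tgt <- n; tgt[i] <- tgt[i] + 1L
          ii <- c(ii, add(tgt)); jj <- c(jj, s); xx <- c(xx, p$birth[i])
        } else {
          leak[s] <- leak[s] + p$birth[i]
        }
        diag_out[s] <- diag_out[s] + p$birth[i]
      }
      if (p$death[i] > 0) {
        tgt <- n; tgt[i] <- tgt[i] - 1L
        ii <- c(ii, add(tgt)); jj <- c(jj, s); xx <- c(xx, p$death[i])
        diag_out[s] <- diag_out[s] + p$death[i]
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(K)), j = c(jj, seq_len(K)),
                            x = c(xx, -diag_out), dims = c(K, K))
  structure(list(A = A, leak_rate = leak, space = space, params = params),
            class = "bdm_generator")
}

#' Probability distribution on the truncated lattice
#'
#' @param prob Probability vector over the enumerated states.
#' @param space The `state_space` it refers to.
#' @param t Time label.
#' @param leaked Upper bound on probability mass lost to the truncation so
#'   far.  `sum(prob) + leaked` must be 1 within `1e-9`.
#' @return An object of class `lattice_distribution`.
#' @export
lattice_distribution <- function(prob, space, t = 0, leaked = 0) {
  stopifnot(inherits(space, "state_space"),
            length(prob) == nrow(space$states),
            all(prob >= -1e-12), leaked >= -1e-12,
            abs(sum(prob) + leaked - 1) <= 1e-9)
  prob[prob < 0] <- 0
  structure(list(prob = as.numeric(prob), space = space, t = t,
                 leaked = max(leaked, 0)),
            class = "lattice_distribution")
}

#' @rdname lattice_distribution
#' @param state Population vector receiving all mass.
#' @return `delta_distribution()` returns a point mass at `state`.
#' @export
delta_distribution <- function(space, state) {
  idx <- state_index(space, state)
  if (is.na(idx)) stop("state outside the truncated lattice", call. = FALSE)
  p <- numeric(nrow(space$states))
  p[idx] <- 1
  lattice_distribution(p, space)
}

#' @export
print.lattice_distribution <- function(x, ...) {
  cat(sprintf("Lattice distribution: %d states (N = %d, n_max = %d), t = %g\n",
              length(x$prob), x$space$N, x$space$n_max, x$t))
  cat(sprintf("  retained mass %.10f, leaked <= %.3e\n", sum(x$prob), x$leaked))
  invisible(x)
}

# Action of expm(A * t) on v by scaling + truncated Taylor series.
# Substeps keep ||A|| * h of order one so the series is well conditioned.
.expm_action <- function(A, v, t) {
  if (t == 0) return(v)
  nrm <- max(Matrix::colSums(abs(A)))
  m <- max(1L, ceiling(nrm * t))
  h <- t / m
  for (s in seq_len(m)) {
    term <- v
    w <- v
    for (k in seq_len(200L)) {
      term <- as.numeric(A %*% term) * (h / k)
      w <- w + term
      if (sum(abs(term)) < 1e-16 * max(sum(abs(w)), 1e-300)) break
    }
    v <- w
  }
  v
}

#' Transient solution of the master equation
#'
#' Propagates a lattice distribution forward by time `t` under the truncated
#' generator: `P(t) = expm(A t) P(0)`.  Small state spaces use a dense matrix
#' exponential; larger ones a scaled truncated-Taylor action of the sparse
#' generator (both agree to well below the reported tolerances).  Mass lost
#' to the truncation is added to `leaked`; a warning is raised if it exceeds
#' `leak_tol` (pick a larger `n_max` in that case).
#'
#' @inheritParams build_generator
#' @param P0 A [lattice_distribution()] (normalized up to previous leakage).
#' @param t Time increment (>= 0).
#' @param method `"auto"` (default), `"dense"` or `"sparse"`.
#' @param leak_tol Warn when the accumulated leaked mass exceeds this.
#' @return The propagated [lattice_distribution()].
#' @export
evolve_distribution <- function(P0, params, t, method = c("auto", "dense", "sparse"),
                                leak_tol = 1e-6) {
  stopifnot(inherits(P0, "lattice_distribution"), t >= 0)
  method <- match.arg(method)
  if (t == 0) return(P0)
  gen <- build_generator(params, P0$space$n_max)
  stopifnot(gen$space$N == P0$space$N)
  K <- length(P0$prob)
  p <- if (method == "dense" || (method == "auto" && K <= 600)) {
    E <- as.matrix(Matrix::expm(gen$A * t))
    as.numeric(E %*% P0$prob)
  } else {
    .expm_action(gen$A, P0$prob, t)
  }
  p[p < 0 & p > -1e-12] <- 0
  leaked <- P0$leaked + max(0, sum(P0$prob) - sum(p))
  if (leaked > leak_tol)
    warning(sprintf("leaked probability mass %.3e exceeds leak_tol = %.1e; increase n_max",
                    leaked, leak_tol), call. = FALSE)
  lattice_distribution(p, P0$space, t = P0$t + t, leaked = leaked)
}

#' Marginal node distributions and moments
#'
#' Reduces a joint lattice distribution to exact per-node marginal pmfs and
#' means.  The means sum to the retained-mass expectation of the total
#' population.
#'
#' @param P A [lattice_distribution()].
#' @return A list with `pmf` (list of data frames `count`, `prob`, one per
#'   node), `means` (length-`N` vector), `mean_total` and `leaked`.
#' @export
lattice_marginals <- function(P) {
  stopifnot(inherits(P, "lattice_distribution"))
  sts <- P$space$states
  N <- P$space$N
  pmf <- lapply(seq_len(N), function(j) {
    tab <- tapply(P$prob, factor(sts[, j], levels = 0:P$space$n_max), sum)
    tab[is.na(tab)] <- 0
    data.frame(count = 0:P$space$n_max, prob = as.numeric(tab))
  })
  means <- as.numeric(crossprod(P$prob, sts))
  list(pmf = pmf, means = means, mean_total = sum(means), leaked = P$leaked)
}
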