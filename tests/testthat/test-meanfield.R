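test_that("interior flow vanishes at the centre and conserves the total", {
  pa <- p3(mu = 1.8)
  expect_equal(interior_flow(c(1, 1, 1) * 500, pa), rep(0, 3),
               tolerance = 1e-12)
  set.seed(3)
  m <- runif(3, 10, 100)
  expect_lt(abs(sum(interior_flow(m, pa))), 1e-10)
})

test_that("interior solution is an exponential spiral with the predicted rates", {
  pa <- p3(r = 1.3, rho = 0.7, mu = 1.6)
  a <- pa$mu - 1.5 * pa$r            # radial growth rate
  b <- sqrt(3) / 2 * pa$r * pa$rho   # angular frequency
  m0 <- c(400, 320, 280)
  centre <- rep(1000 / 3, 3)
  ts <- seq(0, 2, by = 0.25)
  M <- meanfield_interior_solution(pa, m0, ts)
  dev <- sweep(M, 2, centre)
  radius <- sqrt(rowSums(dev^2))
  expect_equal(radius, radius[1] * exp(a * ts), tolerance = 1e-8)
  # angle in the invariant plane advances at rate b
  u1 <- c(2, -1, -1) / sqrt(6); u2 <- c(0, 1, -1) / sqrt(2)
  ang <- atan2(dev %*% u2, dev %*% u1)
  dang <- diff(as.numeric(ang))
  dang <- (dang + pi) %% (2 * pi) - pi
  expect_equal(abs(dang) / 0.25, rep(b, length(dang)), tolerance = 1e-6)
})

test_that("closed-form interior solution matches an adaptive ODE oracle", {
  skip_if_not_installed("deSolve")
  pa <- p3(mu = 1.9, rho = 0.5)
  B <- interior_generator(pa)
  m0 <- c(500, 300, 200)
  ts <- seq(0, 3, by = 0.5)
  sol <- deSolve::lsoda(y = m0, times = ts,
                        func = function(t, y, p) list(as.numeric(y %*% B)),
                        rtol = 1e-10, atol = 1e-10)
  M <- meanfield_interior_solution(pa, m0, ts)
  expect_lt(max(abs(M - sol[, -1])), 1e-6)
})

test_that("boundary weight and sliding flow match their closed forms", {
  pa <- p3(mu = 1.8)
  expect_equal(boundary_weight(c(0.5, 0, 0.5) * 100, pa, 2), 5 / 6)
  expect_equal(boundary_weight(c(0, 0, 1) * 50, pa, 2), 0)
  # sliding rate at the reference point: d(x1)/dt = 0.28 at theta = 0.6
  m <- c(0.6, 0, 0.4) * 1000
  dm <- boundary_flow(m, pa, 2)
  expect_equal(dm[1] / 1000, 0.28, tolerance = 1e-12)
  expect_equal(dm[2], 0)
  expect_equal(sum(dm), 0, tolerance = 1e-12)
  # zero flow at the unstable boundary equilibrium
  th <- control_parameter(p3(mu = 2.2))
  me <- c(kappa_e(th), 0, 1 - kappa_e(th)) * 10
  expect_equal(boundary_flow(me, p3(mu = 2.2), 2), rep(0, 3),
               tolerance = 1e-12)
  expect_error(boundary_weight(c(0.5, 0, 0.5), p3(mu = 0), 2), "mu = 0")
})

test_that("the sliding flow equals the Filippov blend of the two generators", {
  set.seed(21)
  for (rep in 1:10) {
    r <- runif(1, 0.4, 2); rho <- runif(1, 0.3, 1)
    theta <- runif(1, 0.1, 1.15)
    mu <- (theta * r * rho + 3 * r) / 2
    pa <- model_params(r, rho, mu, 3)
    kb <- kappa_b(theta); ke <- kappa_e(theta)
    x <- runif(1, max(0.01, ke + 0.01), kb - 0.01)
    m <- c(x, 0, 1 - x)
    w <- boundary_weight(m, pa, 2)
    blend <- w * as.numeric(m %*% interior_generator(pa)) +
      (1 - w) * as.numeric(m %*% boundary_generator(pa, 2))
    expect_lt(abs(blend[2]), 1e-12)           # empty node stays pinned
    expect_equal(blend, boundary_flow(m, pa, 2), tolerance = 1e-10)
  }
  # outside the sliding range the boundary cannot hold the trajectory
  expect_error(boundary_flow(c(0.9, 0, 0.1), p3(mu = 1.8), 2),
               class = "loopwave_exit_boundary")
})

test_that("hybrid integration reproduces the regime map", {
  # contracting spiral: amorphous
  tr_a <- integrate_meanfield(p3(mu = 1.0), c(500, 300, 200), t_max = 120)
  expect_equal(tr_a$label, "amorphous")
  expect_lt(max(abs(tr_a$final - 1000 / 3)), 1e-6 * 1000)
  # wave regime from near the centre
  tr_w <- integrate_meanfield(p3(mu = 1.8), c(340, 330, 330), t_max = 120)
  expect_equal(tr_w$label, "limit_cycle")
  # beyond theta_c: must collapse into a vertex
  tr_c <- integrate_meanfield(p3(mu = 2.2), c(340, 330, 330), t_max = 120)
  expect_equal(tr_c$label, "collapsed")
  expect_equal(sort(tr_c$final), c(0, 0, 1000))
  # bistable band 1 < theta < theta_c: both outcomes reachable
  tr_b1 <- integrate_meanfield(p3(mu = 2.05), c(340, 330, 330), t_max = 200)
  expect_equal(tr_b1$label, "limit_cycle")
  tr_b2 <- integrate_meanfield(p3(mu = 2.05), c(40, 0, 960), t_max = 200)
  expect_equal(tr_b2$label, "collapsed")
  # simplex conservation across every region switch
  for (tr in list(tr_a, tr_w, tr_c)) {
    tot <- rowSums(tr$trajectory[, c("m_1", "m_2", "m_3")])
    expect_lt(max(abs(tot - 1000)), 1e-9 * 1000)
    expect_true(all(tr$trajectory[, c("m_1", "m_2", "m_3")] >= -1e-9))
  }
  expect_error(integrate_meanfield(p3(rho = 0), c(1, 1, 1)), "rho = 0")
})

test_that("theta_critical solves the transcendental grazing condition", {
  thc <- theta_critical()
  expect_equal(round(thc, 4), 1.2037)
  l <- function(x) log(x) / x
  expect_lt(abs(l(thc / sqrt(3)) + pi / 6), 1e-8)
  expect_gt(abs(l(1) + pi / 6), 0.1) # sqrt(3) is not a root
  expect_gt(thc, 1); expect_lt(thc, sqrt(3))
})

test_that("limit cycle exists only in (0, theta_c) and is consistent", {
  wc <- limit_cycle(p3(mu = 1.8)) # theta = 0.6
  expect_true(wc$exists)
  expect_equal(wc$frequency, wc$fhat) # r * rho = 1
  expect_equal(wc$frequency * wc$period, 1)
  expect_gt(wc$amplitude, 1); expect_lt(wc$amplitude, 3)
  # scale invariance of fhat: frequency = r * |rho| * fhat(theta)
  wc2 <- limit_cycle(model_params(2, 0.5, (0.6 * 2 * 0.5 + 3 * 2) / 2, 3))
  expect_equal(wc2$fhat, wc$fhat, tolerance = 1e-6)
  expect_equal(wc2$frequency, 2 * 0.5 * wc$fhat, tolerance = 1e-6)
  # mirror symmetry for negative bias
  wcm <- limit_cycle(p3(rho = -1, mu = 1.8))
  expect_equal(wcm$frequency, wc$frequency, tolerance = 1e-10)
  expect_equal(wcm$amplitude, wc$amplitude, tolerance = 1e-10)
  # no cycle outside the window
  expect_false(limit_cycle(p3(mu = 1.2))$exists)   # theta < 0
  expect_false(limit_cycle(p3(mu = 2.2))$exists)   # theta > theta_c
})

test_that("cycle grazes the boundary equilibrium at the analytic critical point", {
  expect_lt(abs(grazing_theta() - theta_critical()), 1e-3)
})

test_that("scaled frequency follows the logarithmic approach to theta_c", {
  thc <- theta_critical()
  ks <- 2:5
  fh <- vapply(ks, function(k)
    limit_cycle(p3(mu = (thc - 10^(-k) + 3) / 2))$fhat, numeric(1))
  y <- 1 / fh # should be linear in -log|theta - theta_c|
  fit <- stats::lm(y ~ ks)
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_gt(stats::coef(fit)[2], 0)
})

test_that("wave characteristics curve is monotone and bounded by theta_c", {
  tab <- wave_characteristics_curve(p3(), c(0.3, 0.6, 0.9, 1.1, 1.4))
  expect_true(all(tab$exists[1:4]))
  expect_false(tab$exists[5])
  expect_true(all(diff(tab$fhat[1:4]) < 0))
  expect_true(all(diff(tab$amplitude[1:4]) > 0))
  expect_true(attr(tab, "fhat_decreasing"))
  expect_true(attr(tab, "amplitude_increasing"))
})
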