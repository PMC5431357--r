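test_that("migration matrix matches the loop rate structure", {
  # pure forward cycle
  M <- migration_matrix(p3(r = 1, rho = 1))
  expect_equal(M, matrix(c(-1, 1, 0,
                           0, -1, 1,
                           1, 0, -1), 3, 3, byrow = TRUE))
  # unbiased migration is symmetric with off-diagonals 1/2
  M0 <- migration_matrix(p3(r = 1, rho = 0))
  expect_equal(M0, t(M0))
  expect_equal(sort(unique(M0[row(M0) != col(M0)])), 0.5)
  # N = 4 general case against an independent per-edge enumeration
  pa <- model_params(r = 2, rho = 0.5, mu = 0, N = 4)
  M4 <- migration_matrix(pa)
  ref <- matrix(0, 4, 4)
  for (i in 1:4) {
    ref[i, i] <- -2
    ref[i, i %% 4 + 1] <- 2 * (1 + 0.5) / 2
    ref[i, (i - 2) %% 4 + 1] <- 2 * (1 - 0.5) / 2
  }
  expect_equal(M4, ref)
  expect_equal(rowSums(M4), rep(0, 4), tolerance = 1e-14)
  expect_equal(sum(M4[row(M4) != col(M4)][M4[row(M4) != col(M4)] > 0][1:2]), 2)
})

test_that("generators conserve the mean total population", {
  set.seed(42)
  for (rep in 1:10) {
    r <- runif(1, 0.2, 3); rho <- runif(1, -1, 1); mu <- runif(1, 0, 4)
    N <- sample(3:8, 1)
    pa <- model_params(r, rho, mu, N)
    expect_lt(max(abs(rowSums(migration_matrix(pa)))), 1e-12)
    expect_lt(max(abs(rowSums(interior_generator(pa)))), 1e-12)
    if (N == 3) for (e in 1:3)
      expect_lt(max(abs(rowSums(boundary_generator(pa, e)))), 1e-12)
  }
})

test_that("interior generator reduces correctly and has the uniform null vector", {
  expect_equal(interior_generator(p3(mu = 0)), migration_matrix(p3(mu = 0)))
  B <- interior_generator(p3(mu = 1.8))
  u <- rep(1 / 3, 3)
  expect_equal(as.numeric(u %*% B), rep(0, 3), tolerance = 1e-14)
})

test_that("boundary generator is the mu = 0 migration matrix and respects loop symmetry", {
  expect_equal(boundary_generator(p3(mu = 0), 2), migration_matrix(p3(mu = 0)))
  # cyclic relabeling permutes boundary generators consistently
  pa <- p3(mu = 2)
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 3] <- P[3, 1] <- 1 # node i -> i+1
  B2 <- boundary_generator(pa, 2)
  B3 <- boundary_generator(pa, 3)
  expect_equal(t(P) %*% B2 %*% P, B3, tolerance = 1e-14)
  expect_error(boundary_generator(model_params(1, 1, 2, 4), 2),
               "unsupported")
})

test_that("control parameter matches the reference settings", {
  expect_equal(control_parameter(p3(mu = 1.8)), 0.6)
  expect_equal(control_parameter(p3(mu = 1.5)), 0)
  expect_equal(control_parameter(p3(mu = 2.2)), 1.4)
  expect_equal(control_parameter(p3(mu = 2.08)), 1.16)
  expect_error(control_parameter(p3(rho = 0)), "undefined control parameter")
})

test_that("closed-form eigenvalues agree with numerical eigendecomposition", {
  set.seed(7)
  for (N in 3:12) {
    pa <- model_params(runif(1, 0.3, 2), runif(1, -1, 1), runif(1, 0, 3), N)
    spec <- interior_eigenvalues(pa)
    ev_num <- eigen(interior_generator(pa))$values
    expect_length(spec$eigenvalues, length(ev_num))
    # nearest-neighbour matching: conjugate pairs share a real part, so a
    # lexicographic sort cannot pair the two spectra reliably
    expect_lt(max(vapply(spec$eigenvalues,
                         function(s) min(Mod(s - ev_num)), numeric(1))), 1e-10)
    expect_lt(max(vapply(ev_num,
                         function(s) min(Mod(s - spec$eigenvalues)), numeric(1))), 1e-10)
    # conjugate pairing (plus sigma_0 = 0)
    expect_true(any(spec$eigenvalues == 0))
    expect_lt(max(abs(sort(Im(spec$eigenvalues)) + rev(sort(Im(spec$eigenvalues))))),
              1e-12)
  }
})

test_that("the N = 3 pair is mu - 3r/2 +/- i sqrt(3) r rho / 2", {
  spec <- interior_eigenvalues(p3(r = 1, rho = 1, mu = 0))
  nz <- spec$eigenvalues[spec$eigenvalues != 0]
  expect_equal(sort(Re(nz)), c(-1.5, -1.5))
  expect_equal(sort(Im(nz)), c(-sqrt(3) / 2, sqrt(3) / 2))
  # rho = 0 at the threshold: degenerate real zero crossing
  spec0 <- interior_eigenvalues(p3(rho = 0, mu = 1.5))
  nz0 <- spec0$eigenvalues[spec0$eigenvalues != 0]
  expect_equal(nz0, c(0 + 0i, 0 + 0i))
  expect_false(spec0$is_oscillatory)
})

test_that("stability threshold scales as r(1 - cos(2 pi / N)) and vanishes for large loops", {
  expect_equal(hopf_threshold(p3()), 1.5)
  expect_equal(hopf_threshold(model_params(2, 1, 0, 3)), 3)
  expect_equal(round(hopf_threshold(model_params(1, 1, 0, 10)), 4), 0.191)
  thr <- vapply(3:50, function(N) hopf_threshold(model_params(1, 1, 0, N)),
                numeric(1))
  expect_true(all(diff(thr) < 0))
  expect_lt(hopf_threshold(model_params(1, 1, 0, 1000)), 1e-4)
  # at N = 10 the leading eigenvalue crosses zero at mu ~ 0.19
  specN <- interior_eigenvalues(model_params(1, 1, 0.19, 10))
  expect_lt(max(Re(specN$eigenvalues)), 2e-3)
})

test_that("boundary thresholds and the exit-weight identity", {
  expect_equal(kappa_b(0), 0.5)
  expect_equal(kappa_e(1), 0)
  expect_equal(kappa_b(0.6), 0.6)
  expect_equal(kappa_e(1.4), 1 / 7)
  expect_error(kappa_e(0), "undefined")
  # w evaluated at the exit threshold equals exactly 1
  set.seed(11)
  for (rep in 1:8) {
    r <- runif(1, 0.3, 2); rho <- runif(1, 0.2, 1)
    theta <- runif(1, 0.05, 1.15)
    mu <- (theta * r * rho + 3 * r) / 2
    pa <- model_params(r, rho, mu, 3)
    nbar <- runif(1, 10, 1000)
    kb <- kappa_b(theta)
    m <- c(kb, 0, 1 - kb) * nbar
    expect_equal(boundary_weight(m, pa, 2), 1, tolerance = 1e-12)
  }
})
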