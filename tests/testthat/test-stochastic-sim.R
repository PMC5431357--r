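test_that("propensities match hand-enumerated rates", {
  p <- propensities(c(2, 1, 0), p3(mu = 2))
  expect_equal(p$forward, c(2, 1, 0))
  expect_equal(p$backward, c(0, 0, 0))
  expect_equal(p$birth, c(4, 2, 0))
  expect_equal(p$death, c(3, 3, 0)) # mu * n_tot / Z at populated nodes only
  expect_equal(p$total, 15)
  # empty system
  p0 <- propensities(c(0, 0, 0), p3(mu = 2))
  expect_equal(p0$total, 0)
})

test_that("total birth rate equals total death rate for every state", {
  set.seed(5)
  for (rep in 1:20) {
    pa <- model_params(runif(1, 0.3, 2), runif(1, -1, 1), runif(1, 0, 3),
                       sample(3:6, 1))
    n <- rpois(pa$N, 3)
    p <- propensities(n, pa)
    expect_equal(sum(p$birth), sum(p$death), tolerance = 1e-12)
    expect_true(all(p$death[n == 0] == 0))
  }
})

test_that("a fully biased single particle only hops forward", {
  p <- propensities(c(5, 0, 0), p3(rho = 1, mu = 0))
  expect_equal(p$backward, c(0, 0, 0))
  expect_equal(p$forward, c(5, 0, 0))
  set.seed(1)
  st <- system_state(c(1, 0, 0))
  pa <- p3(rho = 1, mu = 0)
  for (k in 1:9) {
    res <- gillespie_step(st, pa)
    expect_equal(res$event$kind, "migrate_forward")
    st <- res$state
    expect_equal(which(st$n == 1), (k %% 3) + 1)
  }
})

test_that("event selection follows the propensity fractions", {
  pa <- p3(mu = 2)
  st <- system_state(c(2, 1, 0))
  pr <- propensities(st, pa)
  probs <- c(pr$forward, pr$backward, pr$birth, pr$death) / pr$total
  nm <- paste(rep(c("f", "b", "bi", "d"), each = 3), 1:3)
  n_draw <- 20000
  set.seed(17)
  counts <- stats::setNames(numeric(12), nm)
  kind_codes <- c(migrate_forward = 0, migrate_backward = 1, birth = 2, death = 3)
  for (k in seq_len(n_draw)) {
    res <- gillespie_step(st, pa) # same state each draw: multinomial sample
    idx <- kind_codes[[res$event$kind]] * 3 + res$event$node
    counts[idx] <- counts[idx] + 1
  }
  sigma <- sqrt(n_draw * probs * (1 - probs))
  dev <- abs(counts - n_draw * probs)
  expect_true(all(dev[probs > 0] <= 4 * sigma[probs > 0]))
  expect_true(all(counts[probs == 0] == 0))
})

test_that("the empty system is absorbed", {
  res <- gillespie_step(system_state(c(0, 0, 0)), p3(mu = 1))
  expect_true(res$absorbed)
})

test_that("pure migration conserves the total exactly and runs are reproducible", {
  pa <- p3(rho = 0.5, mu = 0)
  t1 <- simulate_bdm(pa, c(50, 30, 20), t_max = 20, seed = 7)
  expect_true(all(rowSums(t1$states) == 100))
  expect_equal(t1$status, "completed")
  t2 <- simulate_bdm(pa, c(50, 30, 20), t_max = 20, seed = 7)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$times, t2$times)
  t3 <- simulate_bdm(pa, c(50, 30, 20), t_max = 20, seed = 8)
  expect_false(identical(t1$states, t3$states))
})

test_that("extinction truncates and flags the trajectory", {
  tr <- simulate_bdm(p3(mu = 5), c(1, 0, 0), t_max = 50, seed = 3)
  expect_equal(tr$status, "extinct")
  expect_lt(max(tr$times), 50)
  expect_true(is.finite(tr$extinction_time))
  expect_true(all(tr$states >= 0))
})

test_that("event log respects the dynamics", {
  tr <- simulate_bdm(p3(mu = 1.2), c(5, 5, 5), t_max = 5, seed = 12,
                     record_events = TRUE)
  ev <- tr$events
  expect_true(all(diff(ev$t) > 0))
  # replay: deaths never fire at empty nodes, migrations conserve the total
  n <- c(5, 5, 5)
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]; nd <- ev$node[i]
    if (k == "death") expect_gt(n[nd], 0)
    tot0 <- sum(n)
    if (k == "migrate_forward") {
      n[nd] <- n[nd] - 1; n[nd %% 3 + 1] <- n[nd %% 3 + 1] + 1
    } else if (k == "migrate_backward") {
      n[nd] <- n[nd] - 1; n[(nd - 2) %% 3 + 1] <- n[(nd - 2) %% 3 + 1] + 1
    } else if (k == "birth") n[nd] <- n[nd] + 1
    else n[nd] <- n[nd] - 1
    expect_true(all(n >= 0))
    if (startsWith(k, "migrate")) expect_equal(sum(n), tot0)
  }
  # final replayed state matches the last sampled state
  expect_equal(as.numeric(tr$states[nrow(tr$states), ]), n)
})

test_that("ensemble conserves the mean total and equilibrates when unbiased", {
  en <- ensemble_bdm(p3(mu = 1), c(10, 10, 10), n_reps = 200, seed_base = 50,
                     t_max = 1, sample_dt = 0.5)
  tot_t1 <- colSums(sapply(en$trajectories, function(tr) {
    if (tr$status == "extinct" && max(tr$times) < 1) c(0, 0, 0)
    else tr$states[nrow(tr$states), ]
  }))
  se <- stats::sd(tot_t1) / sqrt(200)
  expect_lt(abs(mean(tot_t1) - 30), 3 * se)
  # unbiased pure migration spreads uniformly
  en0 <- ensemble_bdm(p3(rho = 0, mu = 0), c(30, 0, 0), n_reps = 100,
                      seed_base = 10, t_max = 10, sample_dt = 5)
  final <- t(sapply(en0$trajectories, function(tr) tr$states[nrow(tr$states), ]))
  for (j in 1:3) {
    se_j <- stats::sd(final[, j]) / sqrt(100)
    expect_lt(abs(mean(final[, j]) - 10), 3.5 * se_j)
  }
  # degenerate ensemble of one replicate has zero variance
  en1 <- ensemble_bdm(p3(mu = 1), c(5, 5, 5), n_reps = 1, seed_base = 1,
                      t_max = 1, sample_dt = 1)
  expect_true(all(en1$var == 0))
})
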