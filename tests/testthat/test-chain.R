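test_that("transition matrix matches hand-computable cases and is stochastic", {
  cfg0 <- game_config(epsilon = 0, eta = 0)
  M <- transition_matrix(transmitter_strategy(1, 1),
                         receiver_strategy(p0 = 0.7), cfg0)
  for (r in 1:4) expect_equal(unname(M[r, ]), c(0.7, 0, 0.3, 0))

  set.seed(101)
  for (i in 1:20) {
    M <- transition_matrix(rand_transmitter(), rand_receiver(),
                           game_config(epsilon = runif(1, 0, 0.5),
                                       eta = runif(1, 0, 0.5)))
    expect_equal(rowSums(M), setNames(rep(1, 4), rownames(M)),
                 tolerance = 1e-12)
    expect_true(all(M >= 0))
  }

  expect_error(transition_matrix(rand_transmitter(), rand_receiver(),
                                 game_config(N = 3)), "N = 1")
})

test_that("transition rows match a brute-force single-step simulation", {
  set.seed(102)
  tr <- rand_transmitter()
  rc <- rand_receiver()
  cfg <- game_config(epsilon = 1e-3, eta = 0.3)
  M <- transition_matrix(tr, rc, cfg)
  n <- 200000L
  for (state in c("ct", "nf")) {
    emp <- single_step_oracle(tr, rc, cfg, state, n = n)
    se <- sqrt(pmax(M[state, ] * (1 - M[state, ]), 1e-12) / n)
    expect_true(all(abs(emp - M[state, ]) < 4 * se + 1e-4))
  }
})

test_that("stationary distribution matches closed forms and power iteration", {
  cfg0 <- game_config(epsilon = 0, eta = 0)
  v <- stationary_distribution(transmitter_strategy(1, 1),
                               receiver_strategy(p0 = 0.7), cfg0)
  expect_equal(unclass(v), c(v_tc = 0.7, v_fc = 0, v_tn = 0.3, v_fn = 0),
               tolerance = 1e-10)

  # silent receiver: two-state veracity chain closed form
  set.seed(103)
  for (i in 1:10) {
    tr <- rand_transmitter()
    v <- stationary_distribution(tr, receiver_strategy(), cfg0)
    expect_equal(v_false(v), (1 - tr$alpha) / (1 - tr$alpha + tr$beta),
                 tolerance = 1e-9)
    expect_equal(v[["v_tc"]] + v[["v_fc"]], 0, tolerance = 1e-12)
  }

  for (i in 1:100) {
    M <- transition_matrix(rand_transmitter(), rand_receiver(),
                           game_config(epsilon = runif(1, 1e-4, 0.3)))
    v <- stationary_distribution(M)
    expect_equal(unname(unclass(v)), power_iter_stationary(M),
                 tolerance = 1e-9)
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("payoffs are the engagement-weighted utilities and linear in v", {
  mk <- function(vals) structure(setNames(vals, c("v_tc", "v_fc", "v_tn", "v_fn")),
                                 class = "stationary_distribution")
  cfg <- game_config(pi_t = 1, pi_f = -1, b_t = 0, b_f = 1)
  expect_equal(payoffs(mk(c(0.7, 0, 0.3, 0)), cfg)[["receiver"]], 0.7)
  expect_equal(payoffs(mk(c(0, 0, 0.6, 0.4)), cfg), c(receiver = 0, transmitter = 0))
  expect_equal(payoffs(mk(c(0.2, 0.4, 0.3, 0.1)), cfg)[["transmitter"]], 0.4)

  set.seed(104)
  v1 <- runif(4); v2 <- runif(4); a <- 0.3
  expect_equal(payoffs(mk(a * v1 + (1 - a) * v2), cfg),
               a * payoffs(mk(v1), cfg) + (1 - a) * payoffs(mk(v2), cfg))
})

test_that("the enforced constraint holds exactly at noise-free stationarity", {
  set.seed(105)
  cfg0 <- game_config(epsilon = 0, eta = 0)
  for (i in 1:200) {
    tr <- rand_transmitter()
    rc <- rand_receiver()
    v <- stationary_distribution(tr, rc, cfg0)
    expect_lt(abs(enforced_constraint_residual(tr, v)), 1e-10)
  }

  # no feedback: v_f fixed by the baselines, independent of engagement
  tr0 <- transmitter_strategy(0.6, 0.3)
  for (p0 in c(0.1, 0.9)) {
    v <- stationary_distribution(tr0, receiver_strategy(p0 = p0), cfg0)
    expect_equal(v_false(v), (1 - 0.6) / (1 - 0.6 + 0.3), tolerance = 1e-10)
  }

  # residual is O(epsilon) under small execution error
  res <- sapply(1:20, function(i) {
    tr <- rand_transmitter()
    v <- stationary_distribution(tr, rand_receiver(),
                                 game_config(epsilon = 1e-3, eta = 0))
    abs(enforced_constraint_residual(tr, v))
  })
  expect_lt(max(res), 0.05)  # ~ 50 * epsilon worst case
  expect_lt(stats::median(res), 0.01)
})

test_that("simulated rounds reproduce the exact chain and are seed-stable", {
  cs <- canned_strategies()
  sim <- simulate_rounds(cs$always_true, receiver_strategy(p0 = 0.5),
                         game_config(epsilon = 0, eta = 0), rounds = 500,
                         seed = 7)
  expect_true(all(sim$trace$veracity == "t"))

  sim2 <- simulate_rounds(cs$no_feedback, receiver_strategy(p0 = 0.3),
                          game_config(), rounds = 1000, seed = 11)
  sim3 <- simulate_rounds(cs$no_feedback, receiver_strategy(p0 = 0.3),
                          game_config(), rounds = 1000, seed = 11)
  expect_identical(sim2$trace, sim3$trace)

  set.seed(106)
  tr <- rand_transmitter()
  rc <- rand_receiver()
  cfg <- game_config(epsilon = 1e-3)
  Tn <- 100000L
  sim <- simulate_rounds(tr, rc, cfg, rounds = Tn, seed = 13)
  v <- stationary_distribution(tr, rc, cfg)
  emp <- as.numeric(sim$receivers[1, c("v_tc", "v_fc", "v_tn", "v_fn")])
  se <- sqrt(pmax(unclass(v) * (1 - unclass(v)), 1e-12) / Tn)
  # serial correlation inflates the naive binomial SE; allow a wide factor
  expect_true(all(abs(emp - unclass(v)) < 12 * se + 5e-3))

  expect_error(simulate_rounds(tr, list(), cfg, rounds = 10), "empty|equal")
})

test_that("empirical distributions converge toward stationarity as T grows", {
  set.seed(107)
  tv <- function(a, b) 0.5 * sum(abs(a - b))
  gaps <- replicate(8, {
    tr <- rand_transmitter()
    rc <- rand_receiver()
    cfg <- game_config(epsilon = 1e-3)
    v <- unclass(stationary_distribution(tr, rc, cfg))
    emp <- function(Tn) {
      s <- simulate_rounds(tr, rc, cfg, rounds = Tn)
      as.numeric(s$receivers[1, c("v_tc", "v_fc", "v_tn", "v_fn")])
    }
    c(short = tv(emp(300L), v), long = tv(emp(30000L), v))
  })
  expect_lt(mean(gaps["long", ]), mean(gaps["short", ]))
})
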