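test_that("Kenyon-cell coding is deterministic and k-sparse", {
  proj <- kc_projection(20L, 1000L, 8L, seed = 3)
  x <- abs(rnorm(20))
  k1 <- kc_encode(x, proj, 0.05)
  k2 <- kc_encode(x, proj, 0.05)
  expect_identical(k1$idx, k2$idx)
  expect_equal(k1$k, 50L)  # ceiling(0.05 * 1000)
  expect_equal(length(k1$idx), 50L)
  expect_true(all(colSums(proj$weights) == 8))  # exact fan-in per KC

  z <- kc_encode(rep(0, 20), proj, 0.05)
  expect_true(z$zero)
  expect_equal(length(z$idx), 0L)
})

test_that("random projections decorrelate independent inputs", {
  # overlap of the active sets for independent inputs matches the
  # hypergeometric expectation k^2 / n_kc
  n_kc <- 400L; f <- 0.05; k <- ceiling(f * n_kc)
  set.seed(5)
  ov <- replicate(200, {
    proj <- kc_projection(30L, n_kc, 6L, seed = sample.int(1e6, 1))
    a <- kc_encode(abs(rnorm(30)), proj, f)
    b <- kc_encode(abs(rnorm(30)), proj, f)
    length(intersect(a$idx, b$idx))
  })
  expected <- k^2 / n_kc
  # hypergeometric SD of the per-draw overlap
  sd1 <- sqrt(k * (k / n_kc) * (1 - k / n_kc) * (n_kc - k) / (n_kc - 1))
  expect_lt(abs(mean(ov) - expected), 3 * sd1 / sqrt(200))
})

test_that("MBON readout is zero before learning and tabular for one-hot codes", {
  mb <- mb_state(100L, 3L, w0 = 0.5, alpha = 0.2, gamma = 0.9)
  proj <- kc_projection(10L, 100L, 4L, seed = 1)
  kc <- kc_encode(abs(rnorm(10)), proj, 0.05)
  expect_equal(q_forward(kc, mb), rep(0, 3))

  # one-hot coding: each state reads its own row
  projI <- kc_projection_identity(4L)
  mbI <- mb_state(4L, 2L, w0 = 2, alpha = 0.5, gamma = 0)
  kcs <- kc_encode(c(0, 1, 0, 0), projI, 1 / 4)
  expect_equal(kcs$idx, 2L)
  ro <- mbon_readout(kcs, mbI)
  dan <- dan_td(1, 0, 0, 0, trace_buffer(kcs, 1L, ro$q_plus[1], ro$q_minus[1]),
                0)
  mbI <- apply_plasticity(mbI, trace_buffer(kcs, 1L, ro$q_plus[1],
                                            ro$q_minus[1]), dan)
  expect_equal(q_forward(kcs, mbI)[1], 0.5 * 1)  # alpha * delta exactly
  expect_equal(q_forward(kc_encode(c(1, 0, 0, 0), projI, 1 / 4), mbI),
               c(0, 0))
})

test_that("action selection implements greedy, epsilon-greedy and softmax", {
  q <- c(0.2, 0.9, 0.9, -1)
  expect_equal(select_action(q, "greedy"), 2L)  # lowest index on ties
  set.seed(7)
  expect_equal(select_action(q, "epsilon_greedy", epsilon = 0), 2L)

  set.seed(9)
  draws <- replicate(10000, select_action(rep(0, 4), "epsilon_greedy",
                                          epsilon = 1))
  freq <- tabulate(draws, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))

  set.seed(11)
  hot <- replicate(1000, select_action(c(0, 1), "softmax", beta = 1000))
  expect_gte(mean(hot == 2L), 0.999)

  expect_error(select_action(q, "epsilon_greedy", epsilon = 2), "epsilon")
  expect_error(select_action(q, "softmax", beta = -1), "beta")
})

test_that("DAN signals encode direct reinforcement and the RPE", {
  expect_equal(dan_direct(0, 0)$combined, 0)
  expect_equal(dan_direct(1, 0)$combined, 1)
  expect_equal(dan_direct(0.3, 0.5)$combined, -0.2)
  expect_error(dan_direct(-1, 0), "valence")

  expect_equal(dan_rpe(1, 0, 0, 0)$combined, 1)      # full surprise
  expect_equal(dan_rpe(1, 0, 1, 0)$combined, 0)      # fully predicted
  expect_equal(dan_rpe(0.2, 0.7, 0.1, 0.4)$combined,
               (0.2 - 0.7) - (0.1 - 0.4))
})

test_that("conditioning error decays as (1 - alpha)^n and extinction stays non-negative", {
  proj <- kc_projection(10L, 200L, 4L, seed = 2)
  kc <- kc_encode(abs(rnorm(10)), proj, 0.05)
  mb <- mb_state(200L, 1L, w0 = 2, alpha = 0.25, gamma = 0)
  cond <- run_mb_conditioning(mb, kc, r_plus = 1, trials = 20L)
  expect_equal(cond$errors, (1 - 0.25)^(0:19), tolerance = 1e-9)
  expect_true(all(diff(abs(cond$errors)) <= 0))  # monotone approach

  ext <- run_mb_conditioning(cond$mb, kc, r_plus = 0, trials = 40L)
  expect_lt(abs(utils::tail(ext$q, 1)), 1e-3)
  expect_gte(min(ext$mb$w_plus, ext$mb$w_minus), 0)
})

test_that("the latency-split DAN signal equals the SARSA TD error", {
  tr <- trace_buffer(NULL, 1L, q_plus = 1.5, q_minus = 0)
  # terminal step: combined = R - Q(prev)
  expect_equal(dan_td(1, 0, 0, 0, tr, 0.9)$combined, 1 - 1.5)
  # gamma = 0 reduces to an immediate-reward RPE against Q(prev)
  expect_equal(dan_td(1, 0, 2, 0, tr, 0)$combined, 1 - 1.5)
  # worked example shared with the tabular oracle
  q <- matrix(0, 2, 1); q[1, 1] <- 1.5; q[2, 1] <- 2
  expect_equal(dan_td(1, 0, 2, 0, tr, 0.9)$combined,
               sarsa_delta(q, 1, 1, 1, 2, 1, 0.9))
  expect_equal(dan_td(1, 0, 2, 0, tr, 0.9)$combined, 1.3)
  # no trace (episode start): no DAN output
  expect_null(dan_td(1, 0, 2, 0, NULL, 0.9))
})

test_that("gamma-zero with a zero-latency trace reproduces the RPE circuit", {
  set.seed(13)
  for (i in 1:100) {
    rp <- runif(1); rm <- runif(1); qp <- runif(1); qm <- runif(1)
    tr_now <- trace_buffer(NULL, 1L, qp, qm)
    expect_equal(dan_td(rp, rm, 99, 99, tr_now, 0)$combined,
                 dan_rpe(rp, rm, qp, qm)$combined)
  }
})

test_that("plasticity is gated by the differential DAN drive and never negative", {
  proj <- kc_projection(10L, 100L, 4L, seed = 4)
  kc <- kc_encode(abs(rnorm(10)), proj, 0.05)
  mb <- mb_state(100L, 2L, w0 = 1, alpha = 0.3)
  tr <- trace_buffer(kc, 1L, 0, 0)
  mb2 <- apply_plasticity(mb, tr, list(d_plus = 0.7, d_minus = 0.7,
                                       combined = 0))
  expect_identical(mb2$w_plus, mb$w_plus)
  expect_identical(mb2$w_minus, mb$w_minus)

  set.seed(15)
  for (i in 1:200) {
    dan <- dan_direct(runif(1, 0, 3), runif(1, 0, 3))
    mb <- apply_plasticity(mb, tr, dan)
  }
  expect_gte(min(mb$w_plus, mb$w_minus), 0)
  expect_gt(mb_clip_fraction(mb, warn = FALSE), 0)  # saturation was counted
})

test_that("the MB circuit with one-hot coding equals tabular SARSA step by step", {
  m <- make_gridworld(5L, 5L, gamma = 0.9)
  res <- run_mb_agent(m, episodes = 600L, alpha = 0.3, w0 = 5,
                      epsilon0 = 0.3, decay = 0.995, seed = 2,
                      record_stream = TRUE)
  expect_equal(res$clip_fraction, 0)
  rep <- replay_tabular(res$stream, m$n_states, m$n_actions, 0.3, 0.9,
                        "sarsa")
  expect_lt(max(abs(res$stream$q_updated - rep$q_updated)), 1e-12)
  expect_lt(max(abs(res$stream$delta - rep$deltas)), 1e-12)
  expect_lt(max(abs(res$q_est - rep$q)), 1e-12)
})

test_that("the off-policy variant reads the greedy action (Q-learning)", {
  m <- make_gridworld(3L, 3L, gamma = 0.9)
  res <- run_mb_agent(m, algo = "q_learning", episodes = 300L, alpha = 0.3,
                      w0 = 5, epsilon0 = 0.4, decay = 0.99, seed = 5,
                      record_stream = TRUE)
  rep <- replay_tabular(res$stream, m$n_states, m$n_actions, 0.3, 0.9,
                        "q_learning")
  expect_lt(max(abs(res$q_est - rep$q)), 1e-12)
})

test_that("the MB agent learns the gradient world to the optimal policy", {
  gw <- make_gradient_world(12L)
  expect_true(all(diff(gw$features[, 1]) > 0))
  vi <- value_iteration(gw$mdp)
  nt <- which(!gw$mdp$terminal)

  one_hot <- suppressWarnings(
    run_mb_agent(gw$mdp, episodes = 1200L, alpha = 0.3, w0 = 5,
                 epsilon0 = 1, decay = 0.997, max_steps = 200L, seed = 3))
  expect_gte(mean(one_hot$policy[nt] == vi$policy[nt]), 0.95)

  gwc <- make_gradient_world(12L, n_channels = 24L, tuning_sd = 0.06)
  coarse <- suppressWarnings(
    run_mb_agent(gwc$mdp, features = gwc$features, n_kc = 300L, f = 0.05,
                 episodes = 600L, alpha = 0.1, w0 = 5, epsilon0 = 1,
                 decay = 0.995, max_steps = 200L, seed = 3))
  expect_gte(mean(coarse$policy[nt] == vi$policy[nt]), 0.90)
})
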