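test_that("MBON budget accounting follows the three-per-location rule", {
  expect_equal(mbon_budget(1L)$total, 3L)
  expect_equal(mbon_budget(1L)$selection, 1L)
  expect_equal(mbon_budget(1L)$steering, 2L)
  expect_equal(mbon_budget(0L)$total, 0L)
  b60 <- mbon_budget(60L)
  expect_true(b60$ok)
  expect_equal(b60$total, 180L)
  expect_error(mbon_budget(70L), "budget")
  expect_error(meta_agent(generate_world("empty"), capacity = 70L),
               "budget")
})

test_that("memories are acquired one-shot at rewarded locations, no duplicates", {
  w <- trapline_world()
  set.seed(1)
  agent <- meta_agent(w, capacity = 4L, seed = 1,
                      config = list(learn_views = FALSE))
  # walk the agent (via its true pose) onto feeder 1 and reward it
  p <- pose(w$feeders$x[1], w$feeders$y[1], 0)
  agent$cx <- beeline:::home_state_at(p, w)
  agent <- acquire_memory_on_reward(agent)
  expect_equal(length(agent$store$memories), 1L)
  m <- memory_vector(agent$store, 1)
  expect_equal(m$magnitude * c(cos(m$angle), sin(m$angle)),
               c(w$feeders$x[1], w$feeders$y[1]), tolerance = 1e-6)

  # revisit within the merge radius: no duplicate
  agent$cx <- beeline:::home_state_at(pose(w$feeders$x[1] + 0.5,
                                           w$feeders$y[1], 0), w)
  agent <- acquire_memory_on_reward(agent)
  expect_equal(length(agent$store$memories), 1L)

  # capacity overflow raises (no eviction)
  agent$store$capacity <- 1L
  agent$cx <- beeline:::home_state_at(pose(-20, 3, 0), w)
  expect_error(acquire_memory_on_reward(agent), "capacity")
})

test_that("pre-training stores one accurate memory per feeder", {
  w <- trapline_world()
  set.seed(2)
  agent <- meta_agent(w, capacity = 4L, seed = 2,
                      config = list(learn_views = FALSE,
                                    motor_noise_sd = 0))
  d <- discover_feeders(agent, replenish(w))
  agent <- d$agent
  expect_equal(length(agent$store$memories), 3L)
  for (i in 1:3) {
    err <- sqrt((agent$mem_locs[i, 1] - w$feeders$x[i])^2 +
                  (agent$mem_locs[i, 2] - w$feeders$y[i])^2)
    expect_lt(err, 0.1)
  }
})

test_that("stored-location error grows with outbound path length under PI noise", {
  w <- generate_world("empty", seed = 1)
  set.seed(3)
  err_for <- function(L) {
    mean(replicate(30, {
      hv <- home_vector_state(8L, 1e5)
      for (i in seq_len(L))
        hv <- pi_step(hv, travel_direction(update_heading(0.7, 0.05), 0, 1),
                      1)
      d <- home_vector(hv)
      Mod(d$length * exp(1i * d$angle) - L * exp(0.7i))
    }))
  }
  e <- sapply(c(20, 80, 320), err_for)
  expect_true(all(diff(e) > 0))
})

test_that("semi-MDP meta updates equal tabular SARSA on a two-feeder bandit", {
  # one decision per bout (crop capacity 1), two equidistant feeders with
  # different payouts: the meta Q must converge toward the per-arm net
  # reward, and greedy selection to the richer arm
  w <- generate_world("traplining", seed = 2,
                      config = list(feeder_positions = rbind(c(8, 6),
                                                             c(8, -6)),
                                    feeder_magnitudes = c(1, 0.2),
                                    n_landmarks = 4L))
  set.seed(4)
  agent <- meta_agent(w, capacity = 2L, seed = 4,
                      config = list(learn_views = FALSE, crop_capacity = 1,
                                    motor_noise_sd = 0))
  d <- discover_feeders(agent, replenish(w)); agent <- d$agent
  world <- w
  sel <- integer(0)
  for (b in 1:30) {
    world <- replenish(world)
    bt <- run_bout(agent, world)
    agent <- bt$agent; world <- bt$world
    sel <- c(sel, bt$decisions[1])
  }
  # greedy choice at the nest is the high-payout feeder's slot
  feat <- beeline:::meta_features(agent, w, pose(0, 0, 0))
  kc <- kc_encode(feat, agent$proj_meta, agent$params$f)
  qv <- q_forward(kc, agent$mb_meta)
  rich <- beeline:::f_next_mem(agent, w, 1L) + 1L
  poor <- beeline:::f_next_mem(agent, w, 2L) + 1L
  expect_gt(qv[rich], qv[poor])
  expect_equal(which.max(qv[-1]) + 1L, rich)
  # late selections favour the richer arm
  expect_gt(mean(utils::tail(sel, 10) == rich), 0.5)
})

test_that("bout reward accounting matches the feeder depletion ledger", {
  w <- trapline_world()
  set.seed(5)
  agent <- meta_agent(w, capacity = 4L, seed = 5,
                      config = list(learn_views = FALSE))
  d <- discover_feeders(agent, replenish(w)); agent <- d$agent
  world <- replenish(w)
  bt <- run_bout(agent, world)
  depleted <- which(!bt$world$feeders$active)
  expect_equal(bt$reward, sum(w$feeders$magnitude[depleted]))
  expect_equal(sort(unique(bt$captures)), sort(depleted))
})

test_that("concurrent view learning is a no-op without memories and updates all slots", {
  w <- trapline_world()
  set.seed(6)
  agent <- meta_agent(w, capacity = 4L, seed = 6)
  poses <- scripted_learning_walk(w, n_loops = 2L, max_radius = 6, seed = 1)

  before <- agent$steer
  a2 <- concurrent_view_learning(agent, poses[1:50, ], w)
  # home slot (1) always learns; memory slots untouched while unstored
  expect_false(identical(a2$steer$left$w_l[, 1], before$left$w_l[, 1]))
  expect_identical(a2$steer$left$w_l[, 2:5], before$left$w_l[, 2:5])

  d <- discover_feeders(agent, replenish(w)); agent <- d$agent
  before <- agent$steer
  a3 <- concurrent_view_learning(agent, poses[1:50, ], w)
  for (slot in 1:4)
    expect_false(identical(a3$steer$left$w_l[, slot],
                           before$left$w_l[, slot]))
})

test_that("steering wrt an inactive memory improves while homing on another", {
  w <- trapline_world()
  set.seed(7)
  agent <- meta_agent(w, capacity = 4L, seed = 7,
                      config = list(learn_views = TRUE))
  # store both memories but train views only along a walk (off-policy)
  d <- discover_feeders(agent, replenish(w), walk_loops = 0L)
  agent <- d$agent
  agree_for <- function(agent, slot) {
    set.seed(70)
    ok <- c()
    for (i in 1:60) {
      p <- resolve_collision(w, pose(runif(1, 0, 12), runif(1, -2, 10),
                                     runif(1, -pi, pi)))
      gl <- agent$mem_locs[slot - 1L, ]
      delta <- wrap_angle(atan2(gl[2] - p$y, gl[1] - p$x) - p$kappa)
      if (abs(delta) < 0.3 || abs(delta) > pi - 0.3) next
      tr <- steer(agent$steer, view_features(render_panorama(w, p, 36L)),
                  slot)
      ok <- c(ok, (delta > 0) == (tr > 0))
    }
    mean(ok)
  }
  base2 <- agree_for(agent, 3L)   # memory 2's circuit before any learning
  # home on memory 1 (active goal) while concurrent learning runs
  world <- replenish(w)
  leg <- beeline:::run_leg(agent, world, pose(0.9, 0.2, 0), 2L)
  # plus an orientation walk with concurrent updates (still goal-1 active)
  walk <- scripted_learning_walk(w, n_loops = 3L, max_radius = 8, seed = 2)
  agent2 <- concurrent_view_learning(leg$agent, walk, w)
  after2 <- agree_for(agent2, 3L)
  expect_gt(after2, base2)
})

test_that("disjoint view updates commute", {
  hc <- homing_circuits(n_pn = 108L, n_kc = 100L, seed = 1)
  kcs_a <- list(left = structure(list(idx = 1:5, k = 5L, n_kc = 100L,
                                      zero = FALSE), class = "kc_activation"),
                right = structure(list(idx = 6:10, k = 5L, n_kc = 100L,
                                       zero = FALSE), class = "kc_activation"))
  kcs_b <- list(left = structure(list(idx = 51:55, k = 5L, n_kc = 100L,
                                      zero = FALSE), class = "kc_activation"),
                right = structure(list(idx = 56:60, k = 5L, n_kc = 100L,
                                       zero = FALSE), class = "kc_activation"))
  h1 <- beeline:::hc_update(beeline:::hc_update(hc, kcs_a, 1L, 1, 0),
                            kcs_b, 1L, 0, 1)
  h2 <- beeline:::hc_update(beeline:::hc_update(hc, kcs_b, 1L, 0, 1),
                            kcs_a, 1L, 1, 0)
  expect_equal(h1$left$w_l, h2$left$w_l)
  expect_equal(h1$right$w_r, h2$right$w_r)
})

test_that("a single-feeder world converges to the direct out-and-back route", {
  w <- generate_world("traplining", seed = 3,
                      config = list(feeder_positions = rbind(c(7, 3)),
                                    n_landmarks = 4L))
  set.seed(8)
  agent <- meta_agent(w, capacity = 2L, seed = 8,
                      config = list(learn_views = FALSE))
  d <- discover_feeders(agent, replenish(w)); agent <- d$agent
  world <- w
  lens <- c()
  for (b in 1:15) {
    world <- replenish(world)
    bt <- run_bout(agent, world)
    agent <- bt$agent; world <- bt$world
    if (b > 10 && bt$complete) lens <- c(lens, bt$path_length)
  }
  direct <- 2 * sqrt(7^2 + 3^2)
  expect_gt(length(lens), 0)
  expect_lt(mean(lens), 1.5 * direct)
})

test_that("hierarchy adapts to a depleted goal faster than flat per-step TD", {
  # tabular abstraction of the shortcut world: a 9-state corridor with the
  # nest at state 5, a near goal at 7 and a far goal at 1. The flat agent
  # learns per-step SARSA; the hierarchical agent learns a two-armed
  # semi-MDP bandit whose reward is the net payoff of a whole excursion.
  # After the near goal stops paying, the bandit re-prices it in a couple
  # of bouts while the flat agent must re-propagate values across states.
  make_corridor <- function(pay7) {
    P <- array(0, c(9, 2, 9)); R <- matrix(-0.05, 9, 2)
    for (s in 1:9) {
      P[s, 1, max(1, s - 1)] <- 1
      P[s, 2, min(9, s + 1)] <- 1
    }
    R[2, 1] <- 1          # stepping onto 1 pays (far goal)
    R[6, 2] <- pay7       # stepping onto 7 pays (near goal)
    term <- rep(FALSE, 9); term[c(1, 7)] <- TRUE
    mdp_spec(P, R, gamma = 0.9, terminal = term, start = 5L)
  }
  flat_switch <- function(seed) {
    rich <- make_corridor(1); poor <- make_corridor(0)
    q <- matrix(0, 9, 2)
    run_eps <- function(mdp, q, eps) {
      s <- 5L
      a <- select_action(q[s, ], "epsilon_greedy", epsilon = eps)
      for (t in 1:60) {
        tr <- beeline:::.mdp_step(mdp, s, a)
        if (tr$terminal) {
          q[s, a] <- q[s, a] + 0.3 * (tr$r - q[s, a])
          break
        }
        a2 <- select_action(q[tr$s_next, ], "epsilon_greedy", epsilon = eps)
        q[s, a] <- q[s, a] + 0.3 * sarsa_delta(q, s, a, tr$r, tr$s_next, a2,
                                               0.9)
        s <- tr$s_next; a <- a2
      }
      q
    }
    set.seed(seed)
    for (ep in 1:80) q <- run_eps(rich, q, 0.2)
    for (ep in 1:200) {
      q <- run_eps(poor, q, 0.2)
      if (which.max(q[5, ]) == 1L) return(ep)  # now prefers the far goal
    }
    200L
  }
  hier_switch <- function(seed) {
    set.seed(seed)
    q <- c(0, 0)  # arms: far goal (net 1 - 4*0.05*2), near (1 - 2*0.05*2)
    pay <- function(arm, depleted) {
      r <- if (arm == 2 && depleted) 0 else 1
      r - c(0.4, 0.2)[arm]
    }
    for (b in 1:40) {
      arm <- select_action(q, "epsilon_greedy", epsilon = 0.2)
      q[arm] <- q[arm] + 0.3 * (pay(arm, FALSE) - q[arm])
    }
    for (b in 1:200) {
      arm <- select_action(q, "epsilon_greedy", epsilon = 0.2)
      q[arm] <- q[arm] + 0.3 * (pay(arm, TRUE) - q[arm])
      if (which.max(q) == 1L) return(b)
    }
    200L
  }
  flat <- sapply(1:20, flat_switch)
  hier <- sapply(1:20, hier_switch)
  expect_lt(mean(hier), mean(flat))
})
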