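#' Simulation protocols: traplining, displacement, shortcut
#'
#' The behavioural experiments run as seeded simulation protocols: repeated
#' foraging bouts on replenishing multi-feeder worlds (traplining with
#' brute-force optimum and nearest-neighbour baselines), displacement of a
#' trained agent to a visually familiar location with a zeroed home vector,
#' and route re-planning after a feeder is permanently depleted (shortcut).
#'
#' @name experiments
NULL

# Default traplining layout (feeders A, B, C): the nearest-neighbour
# heuristic from the nest (A first, then B, then C) yields a 44.9-unit
# tour, 13% longer than the optimal order (A, C, B; 39.7 units). Every
# feeder sits several capture radii off the nest-anchored vector of the
# next feeder on the optimal route, so replaying stored vectors from a
# displaced start misses its target widely.
.trapline_layout <- rbind(c(8, -2.5), c(3.5, 9), c(12, 10))

#' Train a foraging agent on a world
#'
#' Convenience wrapper for the standard training protocol: construct a
#' hierarchical agent, pre-train it on the feeder locations (with
#' orientation walks when view learning is on), then run `n_bouts`
#' replenishing foraging bouts with the softmax determinism ramp.
#'
#' @param world a world with feeders.
#' @param seed agent seed.
#' @param n_bouts training bouts.
#' @param capacity vector-memory capacity.
#' @param config [meta_agent()] overrides.
#' @param bout_views keep concurrent view learning on during bouts (the
#'   steering circuits are otherwise trained during the orientation walks
#'   only).
#' @return the trained `meta_agent`.
#' @export
train_forager <- function(world, seed = 1L, n_bouts = 50L, capacity = 4L,
                          config = list(), bout_views = FALSE) {
  set.seed(substream_seed(seed, "train_forager"))
  agent <- meta_agent(world, capacity = capacity, seed = seed,
                      config = config)
  disc <- discover_feeders(agent, replenish(world))
  agent <- disc$agent
  agent$params$learn_views <- agent$params$learn_views && bout_views
  w <- world
  for (b in seq_len(n_bouts)) {
    w <- replenish(w)
    bt <- run_bout(agent, w)
    agent <- bt$agent; w <- bt$world
  }
  agent
}

#' Traplining experiment: route optimization over repeated bouts
#'
#' A fresh agent is pre-trained on the feeder locations, then forages for
#' `n_bouts` bouts on a replenishing world while the softmax determinism
#' parameter ramps up. Per bout the realized feeder order, realized path
#' length and the Euclidean tour length implied by the order are logged;
#' brute-force optimal and nearest-neighbour tours are returned as
#' baselines.
#'
#' @param seeds integer vector of agent seeds (independent replicates).
#' @param n_bouts bouts per seed.
#' @param world_seed seed of the (shared) world.
#' @param world_config overrides for [generate_world()]; the default feeder
#'   layout makes the nearest-neighbour order suboptimal.
#' @param agent_config overrides for [meta_agent()].
#' @param capacity memory capacity (>= number of feeders).
#' @return list `results` (data.frame: seed, bout, beta, order, complete,
#'   reward, path_length, tour_length), `baselines` ([route_baselines()]),
#'   `world`.
#' @export
run_traplining_experiment <- function(seeds = 1:20, n_bouts = 50L,
                                      world_seed = 1L,
                                      world_config = list(),
                                      agent_config = list(),
                                      capacity = 4L) {
  wcfg <- utils::modifyList(
    list(feeder_positions = .trapline_layout, n_landmarks = 12L), world_config)
  world0 <- generate_world("traplining", seed = world_seed, config = wcfg)
  acfg <- utils::modifyList(list(executor = "pi", learn_views = FALSE),
                            agent_config)
  rows <- list()
  for (sd in seeds) {
    set.seed(substream_seed(sd, "traplining"))
    agent <- meta_agent(world0, capacity = capacity, seed = sd,
                        config = acfg)
    disc <- discover_feeders(agent, replenish(world0))
    agent <- disc$agent
    world <- world0
    for (b in seq_len(n_bouts)) {
      world <- replenish(world)
      bt <- run_bout(agent, world)
      agent <- bt$agent; world <- bt$world
      ord <- unique(bt$captures)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd, bout = b, beta = bt$beta,
        order = paste(ord, collapse = "-"),
        complete = bt$complete &&
          length(ord) == nrow(world0$feeders),
        reward = bt$reward, path_length = bt$path_length,
        tour_length = if (length(ord) == nrow(world0$feeders))
          order_tour_length(world0, ord) else NA_real_)
    }
  }
  list(results = do.call(rbind, rows), baselines = route_baselines(world0),
       world = world0)
}

#' Asymptotic tour length of a traplining run
#'
#' Mean order-implied tour length over the last `tail_bouts` complete bouts
#' of each seed.
#'
#' @param tl result of [run_traplining_experiment()].
#' @param tail_bouts how many final bouts per seed to average.
#' @return named numeric: `asymptotic`, `optimal`, `nn`.
#' @export
traplining_summary <- function(tl, tail_bouts = 10L) {
  res <- tl$results
  per_seed <- vapply(split(res, res$seed), function(d) {
    d <- d[order(d$bout), ]
    v <- d$tour_length[d$complete]
    if (length(v) == 0L) return(NA_real_)
    mean(utils::tail(v, tail_bouts))
  }, numeric(1))
  c(asymptotic = mean(per_seed, na.rm = TRUE),
    optimal = tl$baselines$optimal, nn = tl$baselines$nn)
}

# one greedy evaluation bout to read out the learned route order
greedy_route <- function(agent, world) {
  bt <- run_bout(agent, replenish(world), beta = 1e6, learn = FALSE)
  unique(bt$captures)
}

#' Displacement experiment: view-based route continuation with zero PI
#'
#' A trained agent is displaced to the location of a feeder on its learned
#' route with its home vector zeroed. It then runs its normal
#' decide-and-travel loop on vision alone (the meta-controller picks
#' sub-goals from the compass-aligned view, legs execute on visual
#' steering, up to `max_legs` decisions); success means capturing the
#' feeder that follows the start feeder in the learned route. Two
#' baselines run through the same harness: a vector-sequence agent that
#' replays the stored outbound vector of the correct next feeder through
#' PI steering (which, with a zeroed home vector, aims at the wrong
#' absolute location), and a random-heading straight flight.
#'
#' @param agent a trained [meta_agent()].
#' @param world the training world.
#' @param n_trials displacement trials.
#' @param seed trial seed.
#' @param jitter_sd SD of the start-position jitter around the feeder.
#' @param max_legs decision budget after displacement.
#' @param leg_timeout step budget per displaced leg.
#' @return list `capture_rate`, `vector_baseline_rate`, `random_rate`,
#'   `route` (learned order), `trials` (per-trial data.frame).
#' @export
run_displacement_test <- function(agent, world, n_trials = 20L, seed = 1L,
                                  jitter_sd = 0.5, max_legs = 3L,
                                  leg_timeout = 250L) {
  par <- agent$params
  route <- greedy_route(agent, world)
  if (length(route) < 2L)
    stop("run_displacement_test: agent has not learned a multi-feeder route",
         call. = FALSE)
  set.seed(substream_seed(seed, "displacement"))
  eval_agent <- agent
  eval_agent$params$learn_views <- FALSE
  eval_agent$params$executor <- "visual"
  eval_agent$params$acquire <- FALSE
  eval_agent$params$timeout <- leg_timeout
  f <- world$feeders
  rows <- list()
  for (tr in seq_len(n_trials)) {
    wtest <- replenish(world)
    i_pos <- sample.int(length(route) - 1L, 1L)
    fi <- route[i_pos]; f_next <- route[i_pos + 1L]
    start <- resolve_collision(wtest,
      pose(f$x[fi] + stats::rnorm(1, 0, jitter_sd),
           f$y[fi] + stats::rnorm(1, 0, jitter_sd),
           stats::runif(1, -pi, pi)))
    # hierarchical visual agent: normal decision loop, zeroed home vector
    eval_agent$cx <- home_vector_state(8L, 1000)
    p <- start
    vis_hit <- FALSE
    sel1 <- NA_integer_
    for (d in seq_len(max_legs)) {
      feat <- meta_features(eval_agent, wtest, p)
      kc <- kc_encode(feat, eval_agent$proj_meta, par$f)
      qm <- q_forward(kc, eval_agent$mb_meta)
      qm[!slot_available(eval_agent, p, wtest$capture_radius)] <- -Inf
      qm[1L] <- -Inf   # foraging motivation: the nest is not a target
      a <- which.max(qm)
      if (d == 1L) sel1 <- a
      leg <- run_leg(eval_agent, wtest, p, a)
      wtest <- leg$world; p <- leg$p
      if (f_next %in% leg$captured) { vis_hit <- TRUE; break }
    }
    # vector-sequence baseline: correct next target, but steered by the
    # stored vector from a zeroed home vector
    wb <- replenish(world)
    vb_goal <- eval_agent$mem_locs[f_next_mem(eval_agent, wb, f_next), ]
    vb_hit <- .straight_capture(wb, start, atan2(vb_goal[2], vb_goal[1]),
                                sqrt(sum(vb_goal^2)), f_next, par)
    # random-heading baseline
    rnd_hit <- .straight_capture(wb, start, stats::runif(1, -pi, pi),
                                 leg_timeout * par$speed * par$dt, f_next,
                                 par)
    rows[[tr]] <- data.frame(trial = tr, start_feeder = fi,
                             target = f_next, selected_slot = sel1,
                             visual = vis_hit, vector = vb_hit,
                             random = rnd_hit)
  }
  trials <- do.call(rbind, rows)
  list(capture_rate = mean(trials$visual),
       vector_baseline_rate = mean(trials$vector),
       random_rate = mean(trials$random),
       route = route, trials = trials)
}

# index of the stored memory closest to feeder `fi`'s true location
f_next_mem <- function(agent, world, fi) {
  f <- world$feeders
  d <- sqrt((agent$mem_locs[, 1L] - f$x[fi])^2 +
              (agent$mem_locs[, 2L] - f$y[fi])^2)
  which.min(d)
}

# fly straight along `ang` for (at most) distance `dist`; did we pass within
# capture radius of feeder `target`?
.straight_capture <- function(world, start, ang, dist, target, par) {
  p <- pose(start$x, start$y, ang)
  travelled <- 0
  while (travelled < dist) {
    p <- step_kinematics(p, 0, par$speed, par$dt, par$motor_noise_sd,
                         world$arena_radius)
    travelled <- travelled + par$speed * par$dt
    if (sqrt((p$x - world$feeders$x[target])^2 +
               (p$y - world$feeders$y[target])^2) <= world$capture_radius)
      return(TRUE)
  }
  FALSE
}

#' Shortcut experiment: policy switch after feeder depletion
#'
#' The agent trains on a world with a near feeder C and a far feeder B,
#' both rewarded. C is then permanently depleted. The greedy meta-choice
#' probed at the nest is logged every bout: the switch bout is the first
#' post-depletion bout at which the greedy selection becomes B. Departure
#' points of all B-bound legs are audited; the run is flagged as a novel
#' route if the first post-switch B-leg departs farther than
#' `novelty_radius` from every pre-switch B-leg departure point.
#'
#' @param seed agent seed.
#' @param n_train training bouts with both feeders active.
#' @param n_post bout budget after depletion.
#' @param world_seed,world_config world preset controls.
#' @param agent_config agent overrides.
#' @param deplete if `FALSE`, runs the control (C stays rewarded).
#' @param novelty_radius novelty threshold (arena units).
#' @return list `switched`, `switch_bout` (bouts after depletion, NA if
#'   none), `novel_route`, `probe` (per-bout greedy slot at the nest),
#'   `b_departures` (matrix), `world`.
#' @export
run_shortcut_test <- function(seed = 1L, n_train = 20L, n_post = 40L,
                              world_seed = 1L, world_config = list(),
                              agent_config = list(), deplete = TRUE,
                              novelty_radius = 2) {
  world0 <- generate_world("shortcut", seed = world_seed,
                           config = world_config)
  # feeder 1 = B (far), feeder 2 = C (near); a one-feeder crop makes each
  # training bout a single nest -> feeder -> nest trip, as in nectar
  # foraging, so the C -> B transit can only appear after depletion
  acfg <- utils::modifyList(list(executor = "pi", learn_views = FALSE,
                                 crop_capacity = 1, beta0 = 2,
                                 beta_rate = 1.05),
                            agent_config)
  set.seed(substream_seed(seed, "shortcut"))
  agent <- meta_agent(world0, capacity = 4L, seed = seed, config = acfg)
  disc <- discover_feeders(agent, replenish(world0))
  agent <- disc$agent
  b_slot <- f_next_mem(agent, world0, 1L) + 1L
  c_slot <- f_next_mem(agent, world0, 2L) + 1L
  probe <- integer(0)
  b_dep_pre <- matrix(numeric(0), 0, 2L)  # pre-depletion B-leg departures
  switch_bout <- NA_integer_
  novel <- NA
  world <- world0
  nest_probe <- function(agent, world) {
    feat <- meta_features(agent, world,
                          pose(world$nest[1], world$nest[2], 0))
    kc <- kc_encode(feat, agent$proj_meta, agent$params$f)
    qv <- q_forward(kc, agent$mb_meta)
    avail <- slot_available(agent)
    which.max(replace(qv, !avail, -Inf))
  }
  total_bouts <- n_train + n_post
  for (b in seq_len(total_bouts)) {
    depleted_now <- deplete && b > n_train
    world <- replenish(world, except = if (depleted_now) 2L else integer(0))
    bt <- run_bout(agent, world, record_legs = TRUE)
    agent <- bt$agent; world <- bt$world
    # audit departure points of B-bound legs; the first post-depletion one
    # is novel if no pre-depletion B-leg departed nearby
    pos <- c(world0$nest[1], world0$nest[2])
    for (lg in bt$legs) {
      if (lg$slot == b_slot) {
        if (!depleted_now) {
          b_dep_pre <- rbind(b_dep_pre, matrix(pos, 1L, 2L))
        } else if (is.na(novel)) {
          novel <- nrow(b_dep_pre) == 0L ||
            min(sqrt(rowSums(sweep(b_dep_pre, 2L, pos)^2))) > novelty_radius
        }
      }
      # the next leg departs where this one ended
      pos <- if (lg$captured_goal) unlist(slot_location(agent, lg$slot))
      else pos
    }
    g <- nest_probe(agent, world0)
    probe <- c(probe, g)
    if (depleted_now && is.na(switch_bout) && g == b_slot)
      switch_bout <- b - n_train
  }
  list(switched = !is.na(switch_bout), switch_bout = switch_bout,
       novel_route = novel, probe = probe, b_slot = b_slot,
       c_slot = c_slot, b_departures_pre = b_dep_pre, world = world0)
}
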