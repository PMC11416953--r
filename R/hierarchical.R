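#' Hierarchical MB/CX navigation agent
#'
#' The full model: a mushroom-body TD meta-controller whose discrete action
#' space is the store of vector memories (plus "home"), selecting
#' navigational sub-goals from the current (compass-aligned) panoramic view
#' under external reward; path integration and per-memory visual steering
#' circuits execute the selected leg; and every stored memory's steering
#' circuit keeps learning off-policy from its own internal reward at every
#' step, regardless of which memory is active. Decisions fire at bout start,
#' on sub-goal capture, and on timeout (semi-MDP); the external reward
#' accumulated between decisions, minus a per-distance travel cost, is the
#' meta-reward.
#'
#' @name hierarchical_agent
NULL

#' Construct a hierarchical agent
#'
#' Slot convention: meta-action / steering slot 1 is "home"; memory j uses
#' slot j + 1.
#'
#' @param world the world the agent will live in (fixes input dimensions).
#' @param capacity vector-memory capacity.
#' @param seed top-level seed; all wiring and policy substreams derive from
#'   it.
#' @param config named list of parameter overrides, see Details.
#' @details Key parameters (defaults): `n_azimuth` (36), `n_kc_meta` (400),
#'   `n_kc_steer` (400), `f` (0.05), `alpha_meta` (0.3), `gamma` (0.6),
#'   `w0_meta` (5), `alpha_steer` (0.25), `timeout` (400 steps per leg),
#'   `speed` (1), `dt` (0.25), `motor_noise_sd` (0.05), `compass_noise_sd`
#'   (0), `step_cost` (0.05 reward per distance unit — the metabolic travel
#'   cost that makes shorter routes pay), `beta0` (1.5) and `beta_rate`
#'   (1.02) for the per-bout softmax determinism ramp, `merge_radius` (2),
#'   `executor` ("pi", "visual" or "blend"), `learn_views` (TRUE),
#'   `mbon_budget` (200).
#' @return a `meta_agent` object.
#' @export
meta_agent <- function(world, capacity = 4L, seed = 1L, config = list()) {
  par <- utils::modifyList(list(
    n_azimuth = 36L, n_kc_meta = 400L, n_kc_steer = 400L, fan_in = 8L,
    f = 0.05, alpha_meta = 0.3, gamma = 0.6, w0_meta = 5,
    alpha_steer = 0.25, steer_gain = 2, max_turn = pi / 2,
    timeout = 400L, max_decisions = 12L, speed = 1, dt = 0.25,
    motor_noise_sd = 0.05, compass_noise_sd = 0, step_cost = 0.05,
    beta0 = 1.5, beta_rate = 1.02, beta_max = 50, merge_radius = 2,
    executor = "pi", learn_views = TRUE, acquire = TRUE,
    crop_capacity = Inf,
    pi_gain = 4, blend_scale = 3, scan_every = 6L, n_scan = 12L,
    mbon_budget = 200L), config)
  n_pn <- 3L * par$n_azimuth
  n_slots <- capacity + 1L
  agent <- structure(list(
    world_nest = world$nest,
    capacity = capacity, n_slots = n_slots, seed = seed, params = par,
    proj_meta = kc_projection(n_pn, par$n_kc_meta, par$fan_in,
                              seed = substream_seed(seed, "meta_proj")),
    mb_meta = mb_state(par$n_kc_meta, n_slots, w0 = par$w0_meta,
                       alpha = par$alpha_meta, gamma = par$gamma),
    steer = homing_circuits(n_pn, n_slots = n_slots,
                            n_kc = par$n_kc_steer, fan_in = par$fan_in,
                            f = par$f, alpha = par$alpha_steer,
                            gain = par$steer_gain, max_turn = par$max_turn,
                            seed = substream_seed(seed, "steer")),
    store = vector_memory_store(capacity, 8L, 1000),
    cx = home_vector_state(8L, 1000),
    mem_locs = matrix(NA_real_, capacity, 2L),
    bout = 0L), class = "meta_agent")
  mbon_budget(agent)  # construction-time capacity assertion
  agent
}

#' @export
print.meta_agent <- function(x, ...) {
  cat(sprintf(
    "<meta_agent> %d/%d vector memories, %d meta-actions, bout %d\n",
    length(x$store$memories), x$capacity, x$n_slots, x$bout))
  invisible(x)
}

#' Per-hemisphere MBON budget accounting
#'
#' Each memorized location costs at most three MBONs per hemisphere: one
#' selection MBON plus two steering MBONs. Validates the total against the
#' configured biological budget (~200 MBONs per hemisphere in the honeybee).
#'
#' @param agent a [meta_agent()], or an integer number of memorized
#'   locations.
#' @param budget per-hemisphere MBON budget.
#' @return list `n_locations`, `selection`, `steering`, `total`
#'   (per hemisphere), `budget`, `ok`.
#' @export
mbon_budget <- function(agent, budget = NULL) {
  n_loc <- if (inherits(agent, "meta_agent")) {
    budget <- budget %||% agent$params$mbon_budget
    agent$capacity
  } else as.integer(agent)
  budget <- budget %||% 200L
  out <- list(n_locations = n_loc, selection = n_loc,
              steering = 2L * n_loc, total = 3L * n_loc, budget = budget,
              ok = 3L * n_loc <= budget)
  if (!out$ok)
    stop(sprintf(
      "mbon_budget: %d locations need %d MBONs/hemisphere, exceeding the budget of %d",
      n_loc, out$total, budget), call. = FALSE)
  out
}

# compass-aligned PN features of the current panorama (gaze-stabilised view
# used by the meta-controller; steering circuits see the egocentric view)
meta_features <- function(agent, world, p) {
  p <- resolve_collision(world, pose(p$x, p$y, 0))
  view_features(render_panorama(world, p, agent$params$n_azimuth))
}

# softmax selection restricted to available slots
meta_select <- function(qv, avail, beta) {
  idx <- which(avail)
  if (length(idx) == 1L) return(idx)
  z <- beta * (qv[idx] - max(qv[idx]))
  p <- exp(z) / sum(exp(z))
  idx[sample.int(length(idx), 1L, prob = p)]
}

# slot -> target location (nest, or stored memory location)
slot_location <- function(agent, slot) {
  if (slot == 1L) agent$world_nest else agent$mem_locs[slot - 1L, ]
}

slot_available <- function(agent, p = NULL, capture_radius = 1) {
  avail <- c(TRUE, !is.na(agent$mem_locs[, 1L]))
  if (!is.null(p)) {
    # a goal the agent is already standing on is not a travel option
    for (j in which(avail[-1L])) {
      if (sqrt((agent$mem_locs[j, 1L] - p$x)^2 +
                 (agent$mem_locs[j, 2L] - p$y)^2) <= capture_radius)
        avail[j + 1L] <- FALSE
    }
  }
  avail
}

#' One-shot vector-memory acquisition at a rewarded location
#'
#' Stores the current home vector as a new vector memory unless a memory
#' already exists within the merge radius of the (PI-estimated) location or
#' the store is full (which raises: there is no eviction mechanism).
#'
#' @param agent a [meta_agent()].
#' @return the (possibly) updated agent.
#' @export
acquire_memory_on_reward <- function(agent) {
  hv <- home_vector(agent$cx)
  loc <- agent$world_nest + hv$length * c(cos(hv$angle), sin(hv$angle))
  stored <- which(!is.na(agent$mem_locs[, 1L]))
  if (length(stored) > 0L) {
    d <- sqrt((agent$mem_locs[stored, 1L] - loc[1])^2 +
                (agent$mem_locs[stored, 2L] - loc[2])^2)
    if (any(d <= agent$params$merge_radius)) return(agent)
  }
  agent$store <- store_vector_memory(agent$store, agent$cx)
  j <- length(agent$store$memories)
  agent$mem_locs[j, ] <- loc
  agent
}

# internal-reward updates of every slot's steering circuit (off-policy,
# concurrent across all stored memories plus home)
.learn_views_step <- function(agent, kcs, kappa) {
  slots <- c(1L, which(!is.na(agent$mem_locs[, 1L])) + 1L)
  for (s in slots) {
    goal <- if (s == 1L) goal_vector(agent$cx) else
      goal_vector(agent$cx, agent$store, s - 1L)
    rw <- internal_lr_reward(kappa, goal, "graded")
    if (!is.na(rw$delta))
      agent$steer <- hc_update(agent$steer, kcs, s, rw$r_left, rw$r_right)
  }
  agent
}

#' Off-policy concurrent view learning along a pose stream
#'
#' Every stored memory's steering circuit (and the home circuit) receives
#' its own internal left/right reward at every pose and updates, regardless
#' of any active goal. The agent's PI state is set from the true pose
#' (ground-truth path integration).
#'
#' @param agent a [meta_agent()].
#' @param poses data.frame with `x`, `y`, `kappa`.
#' @param world the world (for panoramas).
#' @return the agent with updated steering circuits.
#' @export
concurrent_view_learning <- function(agent, poses, world) {
  for (i in seq_len(nrow(poses))) {
    p <- resolve_collision(world, pose(poses$x[i], poses$y[i],
                                       poses$kappa[i]))
    agent$cx <- home_state_at(p, world)
    feats <- view_features(render_panorama(world, p, agent$params$n_azimuth))
    kcs <- hc_encode(agent$steer, feats)
    agent <- .learn_views_step(agent, kcs, p$kappa)
  }
  agent
}

# low-level leg toward one slot's goal; returns updated agent/world/pose and
# the accumulated external reward, captures and path
run_leg <- function(agent, world, p, slot, record_path = FALSE) {
  par <- agent$params
  goal_loc <- slot_location(agent, slot)
  mem_idx <- if (slot == 1L) NULL else slot - 1L
  r_plus <- 0; r_minus <- 0; path_len <- 0
  captured <- integer(0)
  path <- if (record_path) matrix(NA_real_, par$timeout, 2L) else NULL
  captured_goal <- FALSE
  steps <- 0L
  for (t in seq_len(par$timeout)) {
    if (sqrt((p$x - goal_loc[1])^2 + (p$y - goal_loc[2])^2) <=
        world$capture_radius) {
      captured_goal <- TRUE
      break
    }
    need_view <- par$executor %in% c("visual", "blend") || par$learn_views
    feats <- if (need_view)
      view_features(render_panorama(world, p, par$n_azimuth)) else NULL
    heading <- update_heading(p$kappa, par$compass_noise_sd)
    gd <- phasor_decode(goal_vector(agent$cx, if (is.null(mem_idx)) NULL
                                    else agent$store, mem_idx))
    turn_pi <- if (gd$undefined) 0 else
      max(-par$pi_gain, min(par$pi_gain,
                            par$pi_gain * wrap_angle(gd$angle -
                                                       heading$kappa)))
    turn <- switch(par$executor,
      pi = turn_pi,
      visual = steer(agent$steer, feats, slot),
      blend = {
        w <- min(1, home_vector(agent$cx)$length / par$blend_scale)
        w * turn_pi + (1 - w) * steer(agent$steer, feats, slot)
      })
    p2 <- resolve_collision(world,
                            step_kinematics(p, turn, par$speed, par$dt,
                                            par$motor_noise_sd,
                                            world$arena_radius))
    step_d <- sqrt((p2$x - p$x)^2 + (p2$y - p$y)^2)
    path_len <- path_len + step_d
    r_minus <- r_minus + par$step_cost * step_d
    trav <- atan2(p2$y - p$y, p2$x - p$x)
    if (par$compass_noise_sd > 0)
      trav <- trav + stats::rnorm(1L, 0, par$compass_noise_sd)
    agent$cx <- pi_step(agent$cx,
                        phasor_encode_raw(trav, step_d / par$dt, 8L,
                                          agent$cx$cpu4$baseline), par$dt)
    sr <- sense_and_reward(world, p2, par$n_azimuth)
    world <- sr$world
    if (sr$r_plus > 0) {
      r_plus <- r_plus + sr$r_plus
      captured <- c(captured, sr$feeder)
      # land by the food source; path integration tracks the landing move
      fd <- c(world$feeders$x[sr$feeder], world$feeders$y[sr$feeder])
      land <- resolve_collision(world, pose(fd[1], fd[2], p2$kappa))
      land_d <- sqrt((land$x - p2$x)^2 + (land$y - p2$y)^2)
      if (land_d > 1e-9) {
        agent$cx <- pi_step(agent$cx,
                            phasor_encode_raw(atan2(land$y - p2$y,
                                                    land$x - p2$x),
                                              land_d, 8L,
                                              agent$cx$cpu4$baseline), 1)
        path_len <- path_len + land_d
        p2 <- land
      }
      if (par$acquire) agent <- acquire_memory_on_reward(agent)
      # finding food at the goal location completes the leg
      if (slot != 1L && sqrt(sum((fd - goal_loc)^2)) <=
            agent$params$merge_radius) {
        captured_goal <- TRUE
        p <- p2
        steps <- t
        break
      }
    }
    if (par$learn_views && !is.null(feats)) {
      kcs <- hc_encode(agent$steer, feats)
      agent <- .learn_views_step(agent, kcs, p$kappa)
    }
    if (record_path) path[t, ] <- c(p2$x, p2$y)
    p <- p2
    steps <- t
  }
  list(agent = agent, world = world, p = p, r_plus = r_plus,
       r_minus = r_minus, captured = captured,
       captured_goal = captured_goal, steps = steps,
       path_length = path_len,
       path = if (record_path) path[seq_len(steps), , drop = FALSE]
       else NULL)
}

#' Run one foraging bout
#'
#' Starts at the nest with a zero home vector, runs semi-MDP meta-decisions
#' (softmax over available memories plus home) with low-level legs in
#' between, applies the latency-split TD update to the meta mushroom body at
#' every decision, and terminates on nest capture (after at least one leg)
#' or on the decision/step budget.
#'
#' @param agent a [meta_agent()].
#' @param world the world (feeders should be replenished by the caller).
#' @param beta softmax inverse temperature for this bout (the determinism
#'   parameter); default follows the agent's ramp.
#' @param learn apply meta updates (disable for evaluation probes).
#' @param record_legs keep the decision/leg log.
#' @return list `agent`, `world`, `captures` (feeder indices in capture
#'   order), `reward`, `cost`, `path_length`, `steps`, `complete` (returned
#'   to the nest), `decisions` (slots chosen), `legs` (per-leg summaries).
#' @export
run_bout <- function(agent, world, beta = NULL, learn = TRUE,
                     record_legs = FALSE) {
  par <- agent$params
  agent$bout <- agent$bout + 1L
  beta <- beta %||% min(par$beta_max, par$beta0 *
                          par$beta_rate^(agent$bout - 1L))
  p <- resolve_collision(world,
                         pose(agent$world_nest[1], agent$world_nest[2],
                              stats::runif(1L, -pi, pi)))
  # the home vector is anchored at the nest, so departure starts with the
  # (small) true offset of the nest entrance
  agent$cx <- home_state_at(p, list(nest = agent$world_nest))
  trace <- NULL
  r_acc_p <- 0; r_acc_m <- 0
  captures <- integer(0); decisions <- integer(0)
  total_reward <- 0; total_cost <- 0; total_len <- 0; total_steps <- 0L
  legs <- list()
  complete <- FALSE
  for (d in seq_len(par$max_decisions)) {
    feat <- meta_features(agent, world, p)
    kc <- kc_encode(feat, agent$proj_meta, par$f)
    qv <- q_forward(kc, agent$mb_meta)
    avail <- slot_available(agent, p, world$capture_radius)
    if (d == 1L && any(avail[-1L])) avail[1L] <- FALSE  # bouts start by leaving
    a <- if (total_reward >= par$crop_capacity) 1L  # crop full: homing drive
    else meta_select(qv, avail, beta)
    ro <- mbon_readout(kc, agent$mb_meta)
    if (learn && !is.null(trace)) {
      dan <- dan_td(r_acc_p, r_acc_m, ro$q_plus[a], ro$q_minus[a], trace,
                    par$gamma)
      agent$mb_meta <- apply_plasticity(agent$mb_meta, trace, dan)
    }
    ro2 <- mbon_readout(kc, agent$mb_meta)
    trace <- trace_buffer(kc, a, ro2$q_plus[a], ro2$q_minus[a])
    r_acc_p <- 0; r_acc_m <- 0
    decisions <- c(decisions, a)
    leg <- run_leg(agent, world, p, a, record_path = FALSE)
    agent <- leg$agent; world <- leg$world; p <- leg$p
    r_acc_p <- r_acc_p + leg$r_plus; r_acc_m <- r_acc_m + leg$r_minus
    total_reward <- total_reward + leg$r_plus
    total_cost <- total_cost + leg$r_minus
    total_len <- total_len + leg$path_length
    total_steps <- total_steps + leg$steps
    captures <- c(captures, leg$captured)
    if (record_legs)
      legs[[d]] <- list(slot = a, steps = leg$steps,
                        captured_goal = leg$captured_goal,
                        captured = leg$captured)
    if (a == 1L && leg$captured_goal) {
      complete <- TRUE
      break
    }
  }
  if (learn && !is.null(trace)) {  # terminal semi-MDP update at bout end
    dan <- dan_td(r_acc_p, r_acc_m, 0, 0, trace, par$gamma)
    agent$mb_meta <- apply_plasticity(agent$mb_meta, trace, dan)
  }
  list(agent = agent, world = world, captures = captures,
       reward = total_reward, cost = total_cost, path_length = total_len,
       steps = total_steps, complete = complete, decisions = decisions,
       legs = legs, beta = beta)
}

#' Pre-training: guided discovery of the feeders
#'
#' Emulates the pre-training phase of foraging experiments (animals are
#' shown each feeder): the agent is led nest -> feeder -> nest for every
#' feeder, accumulating genuine path integration on the way, collecting the
#' reward and one-shot storing a vector memory at each feeder. If view
#' learning is enabled, the agent then performs orientation walks around
#' the nest and around every discovered feeder (the learning walks/flights
#' insects show at the nest and at new food sources), during which every
#' goal slot's steering circuit trains concurrently off-policy. The meta
#' policy is untouched.
#'
#' @param agent a fresh [meta_agent()].
#' @param world the world.
#' @param walk_loops,walk_radius orientation-walk geometry.
#' @return list `agent`, `world`.
#' @export
discover_feeders <- function(agent, world, walk_loops = 5L,
                             walk_radius = 10) {
  par <- agent$params
  f <- world$feeders
  for (i in seq_len(nrow(f))) {
    p <- resolve_collision(world,
                           pose(agent$world_nest[1], agent$world_nest[2],
                                atan2(f$y[i], f$x[i])))
    agent$cx <- home_state_at(p, list(nest = agent$world_nest))
    for (t in seq_len(par$timeout)) {
      d <- sqrt((p$x - f$x[i])^2 + (p$y - f$y[i])^2)
      if (d <= world$capture_radius) break
      bearing <- atan2(f$y[i] - p$y, f$x[i] - p$x)
      turn <- max(-par$pi_gain, min(par$pi_gain,
                                    par$pi_gain * wrap_angle(bearing -
                                                               p$kappa)))
      p2 <- resolve_collision(world,
                              step_kinematics(p, turn, par$speed, par$dt,
                                              par$motor_noise_sd,
                                              world$arena_radius))
      step_d <- sqrt((p2$x - p$x)^2 + (p2$y - p$y)^2)
      trav <- atan2(p2$y - p$y, p2$x - p$x)
      if (par$compass_noise_sd > 0)
        trav <- trav + stats::rnorm(1L, 0, par$compass_noise_sd)
      agent$cx <- pi_step(agent$cx,
                          phasor_encode_raw(trav, step_d / par$dt, 8L,
                                            agent$cx$cpu4$baseline),
                          par$dt)
      if (par$learn_views) {
        feats <- view_features(render_panorama(world, p2, par$n_azimuth))
        kcs <- hc_encode(agent$steer, feats)
        agent <- .learn_views_step(agent, kcs, p2$kappa)
      }
      p <- p2
    }
    sr <- sense_and_reward(world, p, par$n_azimuth)
    world <- sr$world
    if (sr$r_plus > 0 || sqrt((p$x - f$x[i])^2 + (p$y - f$y[i])^2) <=
        world$capture_radius) {
      land <- resolve_collision(world, pose(f$x[i], f$y[i], p$kappa))
      land_d <- sqrt((land$x - p$x)^2 + (land$y - p$y)^2)
      if (land_d > 1e-9)
        agent$cx <- pi_step(agent$cx,
                            phasor_encode_raw(atan2(land$y - p$y,
                                                    land$x - p$x),
                                              land_d, 8L,
                                              agent$cx$cpu4$baseline), 1)
      agent <- acquire_memory_on_reward(agent)
    }
  }
  if (agent$params$learn_views && walk_loops >= 1L) {
    centers <- rbind(agent$world_nest, as.matrix(f[, c("x", "y")]))
    for (ci in seq_len(nrow(centers))) {
      walk <- scripted_learning_walk(
        world, n_loops = walk_loops, max_radius = walk_radius,
        seed = substream_seed(agent$seed, paste0("orient_", ci)),
        center = centers[ci, ])
      agent <- concurrent_view_learning(agent, walk, world)
    }
  }
  list(agent = agent, world = world)
}

# replenish depletable feeders between bouts, honouring permanent depletion
replenish <- function(world, except = integer(0)) {
  if (!is.null(world$feeders)) {
    world$feeders$active <- TRUE
    if (length(except) > 0L) world$feeders$active[except] <- FALSE
  }
  world
}

#' Brute-force route baselines for a feeder layout
#'
#' Enumerates all feeder orders (k <= 8) for the closed tour
#' nest -> feeders -> nest: the optimal (shortest) tour and the
#' nearest-neighbour heuristic tour (greedy from the nest).
#'
#' @param world a world with feeders.
#' @return list `optimal` (length), `optimal_order`, `nn` (length),
#'   `nn_order`, `tours` (per-permutation lengths).
#' @export
route_baselines <- function(world) {
  f <- world$feeders
  k <- nrow(f)
  stopifnot(k >= 1L, k <= 8L)
  pts <- rbind(world$nest, as.matrix(f[, c("x", "y")]))
  dmat <- as.matrix(stats::dist(pts))
  perms <- .permutations(k)
  tour_len <- function(ord) {
    idx <- c(1L, ord + 1L, 1L)
    sum(dmat[cbind(idx[-length(idx)], idx[-1L])])
  }
  lens <- apply(perms, 1L, tour_len)
  # nearest-neighbour from the nest
  left <- seq_len(k); cur <- 1L; nn_ord <- integer(0)
  while (length(left) > 0L) {
    nxt <- left[which.min(dmat[cur, left + 1L])]
    nn_ord <- c(nn_ord, nxt)
    cur <- nxt + 1L
    left <- setdiff(left, nxt)
  }
  list(optimal = min(lens), optimal_order = perms[which.min(lens), ],
       nn = tour_len(nn_ord), nn_order = nn_ord, tours = lens)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

# Euclidean tour length of a realized capture order
order_tour_length <- function(world, order) {
  if (length(order) == 0L) return(NA_real_)
  f <- world$feeders
  pts <- rbind(world$nest,
               as.matrix(f[order, c("x", "y"), drop = FALSE]),
               world$nest)
  sum(sqrt(rowSums(diff(pts)^2)))
}
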