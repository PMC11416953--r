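#' Double-opponent visual steering circuits
#'
#' Two hemispheric copies of the canonical mushroom-body circuit learn, from
#' dense internal left/right rewards computed in the central complex, to
#' associate panoramic views with "steer left" / "steer right" premotor
#' drives. Within each hemisphere the left reward reinforces the steer-left
#' MBON by depressing the steer-right pathway and vice versa; ipsilateral
#' integration inverts sign between hemispheres, so the two hemibrains emit
#' competing steer-left and steer-right commands. Several goal slots can
#' share the Kenyon-cell population, each slot owning its own steering MBON
#' pair per hemisphere (one slot per vector memory, plus the nest).
#'
#' @name homing_controller
NULL

#' Construct a pair of hemisphere steering circuits
#'
#' @param n_pn projection-neuron input dimension (see [view_features()]).
#' @param n_slots number of goal slots (1 for plain nest homing).
#' @param n_kc Kenyon cells per hemisphere.
#' @param fan_in PN synapses per KC.
#' @param f KC sparsity.
#' @param alpha steering learning rate.
#' @param w0 baseline KC-to-MBON weight.
#' @param gain premotor gain mapping net MBON drive to turn rate (rad/time).
#' @param max_turn command saturation (rad/time).
#' @param seed wiring seed (each hemisphere gets an independent substream).
#' @return a `homing_circuits` object.
#' @export
homing_circuits <- function(n_pn, n_slots = 1L, n_kc = 400L, fan_in = 8L,
                            f = 0.05, alpha = 0.25, w0 = 0.5, gain = 2,
                            max_turn = pi / 2, seed = 1L,
                            mirror = n_pn %% 3L == 0L) {
  hemi <- function(side) list(
    side = side,
    proj = kc_projection(n_pn, n_kc, fan_in,
                         seed = substream_seed(seed, paste0("hemi_", side))),
    w_l = matrix(w0, n_kc, n_slots),
    w_r = matrix(w0, n_kc, n_slots))
  left <- hemi("left")
  right <- hemi("right")
  if (mirror) {
    # the two hemibrains are anatomical mirror images: the right
    # hemisphere's PN-to-KC wiring is the left's composed with the
    # visual-field mirror, which makes the whole steering circuit exactly
    # equivariant under world mirroring (assumes view_features() layout)
    q <- .mirror_perm(n_pn %/% 3L)
    right$proj$weights <- left$proj$weights[q, , drop = FALSE]
    right$proj$seed <- left$proj$seed
  }
  structure(list(left = left, right = right,
                 n_slots = n_slots, f = f, alpha = alpha, w0 = w0,
                 gain = gain, max_turn = max_turn, n_pn = n_pn,
                 mirror = mirror),
            class = "homing_circuits")
}

# Permutation q such that view_features(mirrored view) equals
# view_features(view)[q]; mirroring reverses azimuth bins about bin 1 and
# swaps the on/off edge channels. q is an involution.
.mirror_perm <- function(naz) {
  sig <- c(1L, rev(seq_len(naz)[-1L]))          # bin mirror
  idx <- sig - 1L; idx[idx == 0L] <- naz        # circular shift for edges
  c(sig, 2L * naz + idx, naz + idx)
}

# KC codes for a feature vector, one per hemisphere
hc_encode <- function(circuits, features) {
  list(left = kc_encode(features, circuits$left$proj, circuits$f),
       right = kc_encode(features, circuits$right$proj, circuits$f))
}

# Depressive cross-pathway update in both hemispheres for one goal slot:
# the left reward multiplicatively depresses the steer-right pathway and
# vice versa, followed by homeostatic rescaling of each synapse pair back
# to the baseline (synaptic scaling). The pairwise weight difference then
# behaves as a bounded integrator of the signed left/right exposure, which
# stays informative under indefinite continual learning instead of both
# channels ratcheting to zero.
hc_update <- function(circuits, kcs, slot, r_left, r_right) {
  if (r_left == 0 && r_right == 0) return(circuits)
  a <- circuits$alpha
  for (side in c("left", "right")) {
    idx <- kcs[[side]]$idx
    if (length(idx) == 0L) next
    h <- circuits[[side]]
    wl <- h$w_l[idx, slot] * (1 - a * r_right)
    wr <- h$w_r[idx, slot] * (1 - a * r_left)
    m <- pmax(wl, wr)
    sc <- ifelse(m > 0, circuits$w0 / m, 1)
    h$w_l[idx, slot] <- wl * sc
    h$w_r[idx, slot] <- wr * sc
    circuits[[side]] <- h
  }
  circuits
}

# signed steer drive (M_l - M_r) of one hemisphere for one slot
hc_drive <- function(hemi, kc, slot) {
  if (kc$k == 0L) return(0)
  (sum(hemi$w_l[kc$idx, slot]) - sum(hemi$w_r[kc$idx, slot])) / kc$k
}

#' Steering command from the current view
#'
#' The left hemibrain's steer-left drive competes with the right hemibrain's
#' steer-right drive; the net command (positive = CCW = leftward) is scaled
#' by the premotor gain and clipped at `max_turn`. Deterministic given the
#' view. `lesion` silences one hemisphere, halving the drive but (by the
#' double-opponent redundancy) preserving its sign.
#'
#' @param circuits a [homing_circuits()].
#' @param features PN features of the current view ([view_features()]).
#' @param slot goal slot.
#' @param lesion `NULL`, `"left"` or `"right"`.
#' @param kcs optional precomputed KC codes (from repeated calls).
#' @return turn rate in `[-max_turn, max_turn]` (radians per unit time).
#' @export
steer <- function(circuits, features, slot = 1L, lesion = NULL, kcs = NULL) {
  kcs <- kcs %||% hc_encode(circuits, features)
  dl <- if (identical(lesion, "left")) 0 else
    hc_drive(circuits$left, kcs$left, slot)
  dr <- if (identical(lesion, "right")) 0 else
    -hc_drive(circuits$right, kcs$right, slot)  # steer-right command
  max(-circuits$max_turn, min(circuits$max_turn, circuits$gain * (dl - dr)))
}

#' Scan-based goal bearing from the steering circuit
#'
#' Insects refine weak steering signals by scanning: the circuit's signed
#' left/right drive is sampled at `n_scan` evenly spaced headings and its
#' first harmonic is decoded. Since a well-trained drive approximates
#' `c * sin(bearing - heading)`, the harmonic's phase (shifted by pi/2)
#' estimates the allocentric goal bearing, coherently averaging the noise of
#' the individual view responses.
#'
#' @param circuits a [homing_circuits()].
#' @param world,p world and position scanned from.
#' @param slot goal slot.
#' @param n_scan number of scan headings.
#' @param n_azimuth panorama bins.
#' @return list `bearing` (radians, allocentric), `strength` (first-harmonic
#'   amplitude; near 0 means no usable signal).
#' @export
steer_scan <- function(circuits, world, p, slot = 1L, n_scan = 12L,
                       n_azimuth = 36L) {
  th <- 2 * pi * (seq_len(n_scan) - 1L) / n_scan
  dr <- vapply(th, function(t)
    steer(circuits, view_features(render_panorama(world,
                                                  pose(p$x, p$y, t),
                                                  n_azimuth)), slot),
    numeric(1))
  z <- sum(dr * exp(1i * th)) * 2 / n_scan
  list(bearing = wrap_angle(Arg(z) + pi / 2), strength = Mod(z))
}

# CX home-vector state matching the agent's true pose (ground-truth PI)
home_state_at <- function(p, world, n_columns = 8L, max_length = 1000) {
  hv <- home_vector_state(n_columns, max_length)
  hv$cpu4 <- phasor_encode_raw(atan2(p$y - world$nest[2],
                                     p$x - world$nest[1]),
                               sqrt((p$x - world$nest[1])^2 +
                                      (p$y - world$nest[2])^2),
                               n_columns, max_length)
  hv
}

#' Train the steering circuits off-policy along a scripted walk
#'
#' At every walk pose the panorama is rendered, Kenyon-cell encoded, and the
#' CX comparator's internal left/right reward (with respect to the nest, or
#' to a stored vector memory) directly reinforces the corresponding steering
#' MBONs in both hemispheres. The walk is the behaviour policy, not the
#' learned one (off-policy); rewards are dense, so no prediction error is
#' computed. Poses where the goal vector vanishes are skipped.
#'
#' @param circuits a [homing_circuits()].
#' @param world the training world.
#' @param walk data.frame of poses from [scripted_learning_walk()].
#' @param store,memory optional [vector_memory_store()] and memory index;
#'   `NULL` trains nest homing.
#' @param slot goal slot receiving the updates.
#' @param mode internal reward mode, `"graded"` (default; magnitude-weighted
#'   learning) or `"binary"`.
#' @param n_azimuth panorama bins.
#' @return the trained `homing_circuits`.
#' @export
train_homing <- function(circuits, world, walk, store = NULL, memory = NULL,
                         slot = 1L, mode = "graded", n_azimuth = 36L) {
  for (i in seq_len(nrow(walk))) {
    p <- resolve_collision(world, pose(walk$x[i], walk$y[i], walk$kappa[i]))
    hv <- home_state_at(p, world)
    goal <- goal_vector(hv, store, memory)
    rw <- internal_lr_reward(p$kappa, goal, mode)
    if (is.na(rw$delta)) next
    feats <- view_features(render_panorama(world, p, n_azimuth))
    kcs <- hc_encode(circuits, feats)
    circuits <- hc_update(circuits, kcs, slot, rw$r_left, rw$r_right)
  }
  circuits
}

#' Closed-loop homing trial
#'
#' Runs sense -> steer -> move until the goal is captured or `max_steps`
#' elapse. Steering is visual (trained circuits), PI-based (proportional
#' turn toward the CX goal vector), or a convex blend weighted by the
#' home-vector length (a long home vector means PI is trustworthy).
#'
#' @param circuits a [homing_circuits()] (may be untrained).
#' @param world the world.
#' @param start starting [pose()].
#' @param store,memory optional memory goal; `NULL` homes to the nest.
#' @param slot steering slot for visual mode.
#' @param mode `"visual"`, `"pi"` or `"blend"`.
#' @param max_steps step budget.
#' @param dt,speed kinematics.
#' @param motor_noise_sd,compass_noise_sd noise levels.
#' @param pi_gain proportional gain of PI steering (per unit time).
#' @param blend_scale home-vector length at which PI fully dominates.
#' @param n_azimuth panorama bins.
#' @param zero_pi start with an (experimentally) zeroed home vector.
#' @return list `log` (t, x, y, kappa, turn), `success`, `steps`,
#'   `path_length`.
#' @export
run_homing_trial <- function(circuits, world, start, store = NULL,
                             memory = NULL, slot = 1L,
                             mode = c("visual", "pi", "blend"),
                             max_steps = 600L, dt = 0.25, speed = 1,
                             motor_noise_sd = 0, compass_noise_sd = 0,
                             pi_gain = 4, blend_scale = 3, n_azimuth = 36L,
                             zero_pi = FALSE) {
  mode <- match.arg(mode)
  goal_loc <- if (is.null(store) || is.null(memory)) world$nest else {
    mv <- memory_vector(store, memory)
    world$nest + mv$magnitude * c(cos(mv$angle), sin(mv$angle))
  }
  hv <- if (zero_pi) home_vector_state(8L, 1000) else
    home_state_at(start, world)
  p <- start
  n <- 0L; path_len <- 0
  log <- matrix(NA_real_, max_steps, 5L,
                dimnames = list(NULL, c("t", "x", "y", "kappa", "turn")))
  success <- FALSE
  for (t in seq_len(max_steps)) {
    if (sqrt((p$x - goal_loc[1])^2 + (p$y - goal_loc[2])^2) <=
        world$capture_radius) {
      success <- TRUE
      break
    }
    heading <- update_heading(p$kappa, compass_noise_sd)
    goal <- goal_vector(hv, store, memory)
    gd <- phasor_decode(goal)
    turn_pi <- if (gd$undefined) 0 else
      max(-pi_gain, min(pi_gain, pi_gain * wrap_angle(gd$angle -
                                                        heading$kappa)))
    turn <- switch(mode,
      pi = turn_pi,
      visual = steer(circuits, view_features(
        render_panorama(world, p, n_azimuth)), slot),
      blend = {
        w <- min(1, home_vector(hv)$length / blend_scale)
        w * turn_pi + (1 - w) * steer(circuits, view_features(
          render_panorama(world, p, n_azimuth)), slot)
      })
    p2 <- resolve_collision(world,
                            step_kinematics(p, turn, speed, dt,
                                            motor_noise_sd,
                                            world$arena_radius))
    step_d <- sqrt((p2$x - p$x)^2 + (p2$y - p$y)^2)
    path_len <- path_len + step_d
    # optic-flow travel direction, read through the (noisy) compass
    trav_ang <- atan2(p2$y - p$y, p2$x - p$x)
    if (compass_noise_sd > 0)
      trav_ang <- trav_ang + stats::rnorm(1L, 0, compass_noise_sd)
    hv <- pi_step(hv, phasor_encode_raw(trav_ang, step_d / dt, 8L,
                                        hv$cpu4$baseline), dt)
    n <- t
    log[t, ] <- c(t * dt, p2$x, p2$y, p2$kappa, turn)
    p <- p2
  }
  list(log = as.data.frame(log[seq_len(n), , drop = FALSE]),
       success = success, steps = n, path_length = path_len,
       final_pose = p)
}
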