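#' Central-complex states: heading, path integration, vector memories
#'
#' The central complex (CX) is modelled at the population-code level: a
#' compass (TB1-like) phasor of unit magnitude carries the current heading, a
#' CPU4-like phasor accumulates the allocentric travel vector into a
#' nest-to-agent home vector, and vector memories are stored as negative
#' imprints of CPU4 snapshots. No ring-attractor dynamics are simulated; the
#' compass is ground truth plus Gaussian noise, as the sky compass is treated
#' as given.
#'
#' @name central_complex
NULL

#' Update the heading (compass) state
#'
#' Encodes the agent's allocentric heading kappa as a unit-magnitude phasor,
#' optionally corrupted by Gaussian compass noise. The noisy value is what all
#' downstream circuits see. Uses the ambient RNG; seed the session for
#' reproducibility.
#'
#' @param kappa true allocentric heading, radians CCW from +x.
#' @param noise_sd compass noise SD, radians.
#' @param n_columns phasor columns (default 8).
#' @param baseline phasor baseline rate.
#' @return list with `kappa` (noisy heading actually encoded), `kappa_true`,
#'   `tb1` (unit phasor), `noise_sd`.
#' @export
update_heading <- function(kappa, noise_sd = 0, n_columns = 8L, baseline = 1) {
  eps <- if (noise_sd > 0) stats::rnorm(1L, 0, noise_sd) else 0
  k <- wrap_angle(kappa + eps)
  list(kappa = k, kappa_true = wrap_angle(kappa),
       tb1 = phasor_encode(k, baseline, n_columns, baseline),
       noise_sd = noise_sd)
}

#' Allocentric travel-direction phasor
#'
#' Rotates the heading phasor by the egocentric drift angle of the optic-flow
#' vector and scales it by speed, yielding a phasor that decodes to the
#' allocentric travel direction with magnitude proportional to speed. This is
#' the phasor-based vector rotation by which heading and egocentric flow
#' combine into travel direction.
#'
#' @param heading a heading state from [update_heading()].
#' @param ego_flow_angle egocentric direction of travel relative to the body
#'   axis (0 = straight ahead, pi/2 = pure leftward sideslip), radians.
#' @param ego_speed ground speed (>= 0), arbitrary distance units per time.
#' @return a [phasor] decoding to angle `kappa + ego_flow_angle`, magnitude
#'   `ego_speed`.
#' @export
travel_direction <- function(heading, ego_flow_angle = 0, ego_speed = 1) {
  stopifnot(ego_speed >= 0)
  p <- heading$tb1
  phasor_encode_raw(heading$kappa + ego_flow_angle, ego_speed,
                    p$n_columns, p$baseline)
}

#' Initialise a CPU4 home-vector accumulator
#'
#' The CPU4 phasor stores the nest-to-agent displacement; the homing drive is
#' its negation, so the home vector is literally zero at the nest. `max_length`
#' sets the largest representable displacement (the phasor baseline);
#' exceeding it during integration is a loud saturation error rather than a
#' silent clip.
#'
#' @param n_columns phasor columns.
#' @param max_length saturation length in arena distance units.
#' @return list with `cpu4` ([phasor]) and `max_length`.
#' @export
home_vector_state <- function(n_columns = 8L, max_length = 1000) {
  list(cpu4 = phasor_encode(0, 0, n_columns, max_length),
       max_length = max_length)
}

#' One path-integration step
#'
#' Accumulates `travel * dt` into the CPU4 phasor. All operations are linear
#' in the first harmonic, so with zero noise the decoded CPU4 vector equals
#' the exact summed displacement.
#'
#' @param state home-vector state from [home_vector_state()].
#' @param travel travel-direction phasor from [travel_direction()].
#' @param dt timestep.
#' @return updated home-vector state.
#' @export
pi_step <- function(state, travel, dt = 1) {
  td <- phasor_decode(travel)
  inc <- phasor_encode_raw(td$angle, td$magnitude * dt,
                           state$cpu4$n_columns, state$cpu4$baseline)
  cpu4 <- phasor_add(state$cpu4, inc)
  if (phasor_decode(cpu4)$magnitude > state$max_length)
    stop("pi_step: CPU4 saturation (home vector exceeds max_length)",
         call. = FALSE)
  state$cpu4 <- cpu4
  state
}

#' Decode the current home vector
#'
#' @param state home-vector state.
#' @return list `angle` (Pi, radians), `length`, `undefined`.
#' @export
home_vector <- function(state) {
  d <- phasor_decode(state$cpu4)
  list(angle = d$angle, length = d$magnitude, undefined = d$undefined)
}

#' Create an empty vector-memory store
#'
#' @param capacity maximum number of memories. There is no eviction: storing
#'   beyond capacity raises (no biological mechanism for memory re-assignment
#'   is assumed).
#' @param n_columns,max_length must match the CPU4 accumulator.
#' @return a `vector_memory_store` object.
#' @export
vector_memory_store <- function(capacity = 8L, n_columns = 8L,
                                max_length = 1000) {
  structure(list(memories = list(), capacity = capacity,
                 n_columns = n_columns, max_length = max_length),
            class = "vector_memory_store")
}

#' Store the current home vector as a vector memory
#'
#' The imprint is the negative of the baseline-subtracted CPU4 snapshot
#' (tangential inhibition onto all columns): activating it against a zero home
#' vector drives the agent out to the remembered location; against a non-zero
#' home vector it yields the direct shortcut.
#'
#' @param store a [vector_memory_store()].
#' @param home home-vector state at the moment of storage.
#' @param label identifier for the memory.
#' @return the store with one more imprint appended.
#' @export
store_vector_memory <- function(store, home, label = NULL) {
  stopifnot(inherits(store, "vector_memory_store"))
  if (length(store$memories) >= store$capacity)
    stop("store_vector_memory: store at capacity (no eviction mechanism)",
         call. = FALSE)
  if (home$cpu4$n_columns != store$n_columns)
    stop("store_vector_memory: mismatched n_columns", call. = FALSE)
  w <- -(home$cpu4$rates - home$cpu4$baseline)
  store$memories[[length(store$memories) + 1L]] <-
    list(w = w, label = label %||% sprintf("m%d", length(store$memories) + 1L))
  store
}

#' Decode a stored memory into the remembered displacement
#'
#' @param store a [vector_memory_store()].
#' @param i memory index.
#' @return list `angle`, `magnitude` of the nest-to-location displacement.
#' @export
memory_vector <- function(store, i) {
  m <- store$memories[[i]]
  phasor_decode(phasor(store$max_length - m$w, baseline = store$max_length,
                       validate = FALSE))
}

#' Goal (shortcut) vector toward a memory, or home
#'
#' Applies the stored inhibitory imprint to the current CPU4 activity and
#' negates the result: the returned phasor decodes to the vector from the
#' agent to the remembered location, `m - h`. With no memory selected the goal
#' is the nest, `-h`.
#'
#' @param home current home-vector state (`h` = nest to agent).
#' @param store a [vector_memory_store()], or NULL for homing.
#' @param i index of the active memory, or NULL for homing.
#' @return a [phasor] decoding to the agent-to-goal vector.
#' @export
goal_vector <- function(home, store = NULL, i = NULL) {
  if (is.null(store) || is.null(i))
    return(phasor_negate(home$cpu4))
  m <- store$memories[[i]]
  imprint <- phasor(home$cpu4$baseline + m$w, baseline = home$cpu4$baseline,
                    validate = FALSE)
  phasor_negate(phasor_add(home$cpu4, imprint))
}

#' Internal left/right reward from the CX goal comparator
#'
#' Compares the goal direction with the current heading: delta =
#' wrap(goal_angle - kappa) in (-pi, pi]. Positive delta means the goal lies
#' to the left (CCW). In `binary` mode one of the rewards is 1; in `graded`
#' mode they are max(0, +/- sin(delta)). A goal directly behind
#' (delta = +/- pi) or dead ahead yields (0, 0); an undefined (zero-magnitude)
#' goal yields (0, 0).
#'
#' @param kappa current heading, radians.
#' @param goal goal phasor from [goal_vector()].
#' @param mode `"binary"` or `"graded"`.
#' @return list `r_left`, `r_right`, `delta`.
#' @export
internal_lr_reward <- function(kappa, goal, mode = c("binary", "graded")) {
  mode <- match.arg(mode)
  d <- phasor_decode(goal)
  if (d$undefined)
    return(list(r_left = 0, r_right = 0, delta = NA_real_))
  delta <- wrap_angle(d$angle - kappa)
  if (mode == "binary") {
    r_left <- as.numeric(delta > 0 && delta < pi)
    r_right <- as.numeric(delta < 0)
  } else {
    r_left <- max(0, sin(delta))
    r_right <- max(0, -sin(delta))
  }
  list(r_left = r_left, r_right = r_right, delta = delta)
}
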