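#' Seeded 2D foraging worlds
#'
#' Synthetic arenas for central-place foraging simulations: a nest, feeders
#' (optionally depletable), and landmark cylinders that give panoramic
#' skyline views their structure. Worlds regenerate bit-identically from
#' seed + config. Coordinates are allocentric Cartesian; angles CCW radians
#' from +x.
#'
#' @name world_env
NULL

#' Generate a world from a preset
#'
#' Presets: `"traplining"` (nest + k feeders with a minimum separation),
#' `"homing"` (nest only), `"shortcut"` (a near feeder C and a far feeder
#' B), `"empty"`. All presets except `"empty"` place beacons — a tower on
#' the nest and a distinctively sized tower beside each feeder — plus
#' scattered low landmark cylinders, so panoramas discriminate locations
#' and carry goal-anchored structure the associative steering learner can
#' use. Any default can be overridden through `config`; in particular
#' `config$feeder_positions` (matrix of x, y rows) pins the feeder layout
#' and `config$beacons = FALSE` drops the towers.
#'
#' @param preset world preset name.
#' @param seed integer seed; the world is a pure function of (preset, seed,
#'   config).
#' @param config named list of overrides: `arena_radius`, `n_feeders`,
#'   `feeder_magnitudes`, `feeder_positions`, `min_feeder_sep`,
#'   `n_landmarks`, `capture_radius`, `depletable`.
#' @return a `world` object.
#' @export
generate_world <- function(preset = c("traplining", "homing", "shortcut",
                                      "empty"),
                           seed = 1L, config = list()) {
  preset <- match.arg(preset)
  cfg <- utils::modifyList(list(
    arena_radius = 50, n_feeders = 3L, feeder_magnitudes = NULL,
    feeder_positions = NULL, min_feeder_sep = 4, n_landmarks = 5L,
    capture_radius = 1, depletable = TRUE, feeder_range = c(6, 16),
    landmark_height = c(1, 2), landmark_radius = c(0.6, 1.4),
    beacons = TRUE), config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, paste0("world_", preset)))
  nest <- c(0, 0)
  feeders <- NULL
  landmarks <- NULL
  if (preset %in% c("traplining", "shortcut")) {
    pos <- cfg$feeder_positions
    if (is.null(pos)) {
      if (preset == "shortcut") {
        # near feeder C, far feeder B roughly opposite sides of C's bearing
        pos <- rbind(c(14, 4), c(6, -2))  # B (far), C (near)
      } else {
        pos <- .place_points(cfg$n_feeders, cfg$feeder_range,
                             cfg$min_feeder_sep)
        if (is.null(pos))
          stop("generate_world: infeasible feeder placement", call. = FALSE)
      }
    }
    mags <- cfg$feeder_magnitudes %||% rep(1, nrow(pos))
    feeders <- data.frame(x = pos[, 1], y = pos[, 2], magnitude = mags,
                          depletable = rep(cfg$depletable, nrow(pos)),
                          active = TRUE)
  }
  if (preset != "empty") {
    # Location beacons: a tall tower marks the nest and each feeder gets a
    # distinctive cluster of small cylinders (the classic cylinder-array
    # arrangement of homing experiments). A correlational view learner
    # needs such goal-anchored visual structure; featureless or uniformly
    # cluttered scenes leave the left/right-of-goal signal unlearnable.
    landmarks <- NULL
    if (cfg$beacons) {
      # the nest tower sits on the nest itself; its collision ring
      # (radius + clearance margin) stays inside the capture radius
      landmarks <- rbind(
        landmarks,
        data.frame(x = nest[1], y = nest[2], radius = 0.55, height = 6))
      if (!is.null(feeders)) {
        # one tower per feeder, just beside it (so the agent can land on
        # the feeder itself); height encodes feeder identity
        for (i in seq_len(nrow(feeders))) {
          ang <- 2 * pi * i / nrow(feeders) + 0.5
          landmarks <- rbind(landmarks, data.frame(
            x = feeders$x[i] + 1.2 * cos(ang),
            y = feeders$y[i] + 1.2 * sin(ang),
            radius = 0.45, height = 2.5 + 1.5 * i))
        }
      }
    }
    nl <- cfg$n_landmarks
    if (nl > 0L) {
      lm <- .place_points(nl, c(4, cfg$arena_radius * 0.6), 2.5,
                          avoid = rbind(nest, as.matrix(
                            if (is.null(feeders)) matrix(0, 0, 2)
                            else feeders[, c("x", "y")])),
                          avoid_dist = 4)
      if (is.null(lm))
        stop("generate_world: infeasible landmark placement", call. = FALSE)
      landmarks <- rbind(landmarks, data.frame(
        x = lm[, 1], y = lm[, 2],
        radius = stats::runif(nrow(lm), cfg$landmark_radius[1],
                              cfg$landmark_radius[2]),
        height = stats::runif(nrow(lm), cfg$landmark_height[1],
                              cfg$landmark_height[2])))
    }
  }
  structure(list(nest = nest, feeders = feeders, landmarks = landmarks,
                 arena_radius = cfg$arena_radius, capture_radius =
                   cfg$capture_radius, seed = seed, preset = preset,
                 config = cfg),
            class = "world")
}

# rejection-sample points in an annulus with minimum pairwise separation
.place_points <- function(n, rrange, min_sep, avoid = NULL, avoid_dist = 0,
                          max_tries = 2000L) {
  pts <- matrix(NA_real_, 0, 2)
  for (tries in seq_len(max_tries)) {
    r <- sqrt(stats::runif(1, rrange[1]^2, rrange[2]^2))
    a <- stats::runif(1, 0, 2 * pi)
    p <- c(r * cos(a), r * sin(a))
    ok <- TRUE
    if (nrow(pts) > 0 &&
        min(sqrt(rowSums(sweep(pts, 2, p)^2))) < min_sep) ok <- FALSE
    if (ok && !is.null(avoid) && nrow(avoid) > 0 &&
        min(sqrt(rowSums(sweep(avoid, 2, p)^2))) < avoid_dist) ok <- FALSE
    if (ok) pts <- rbind(pts, p)
    if (nrow(pts) == n) return(unname(pts))
  }
  NULL
}

#' Construct an agent pose
#'
#' @param x,y position (arena units).
#' @param kappa heading, radians CCW from +x (wrapped to (-pi, pi]).
#' @return a `pose` object.
#' @export
pose <- function(x = 0, y = 0, kappa = 0) {
  stopifnot(is.finite(x), is.finite(y), is.finite(kappa))
  structure(list(x = x, y = y, kappa = wrap_angle(kappa)), class = "pose")
}

#' Render the panoramic skyline at a pose
#'
#' Egocentric azimuthal binning (bin 1 = straight ahead, bins increasing
#' CCW); each bin holds the maximum angular elevation of any landmark
#' cylinder covering that bin's centre direction, 0 where only sky is
#' visible. Rotating the agent by exactly one bin width circularly shifts
#' the view by one bin.
#'
#' @param world a [generate_world()] world.
#' @param p a [pose()].
#' @param n_azimuth number of azimuth bins (default 36).
#' @return numeric vector of `n_azimuth` elevations in `[0, pi/2)`.
#' @export
render_panorama <- function(world, p, n_azimuth = 36L) {
  elev <- numeric(n_azimuth)
  lm <- world$landmarks
  if (is.null(lm) || nrow(lm) == 0L) return(elev)
  centers <- 2 * pi * (seq_len(n_azimuth) - 1L) / n_azimuth
  for (i in seq_len(nrow(lm))) {
    dx <- lm$x[i] - p$x; dy <- lm$y[i] - p$y
    d <- sqrt(dx^2 + dy^2)
    if (d <= lm$radius[i])
      stop("render_panorama: pose inside a landmark (collision)",
           call. = FALSE)
    phi <- wrap_angle(atan2(dy, dx) - p$kappa)  # egocentric bearing
    hw <- asin(min(1, lm$radius[i] / d))        # angular half-width
    el <- atan(lm$height[i] / (d - lm$radius[i]))
    hit <- abs(wrap_angle(centers - phi)) <= hw
    elev[hit] <- pmax(elev[hit], el)
  }
  elev
}

#' Projection-neuron features from a panorama
#'
#' Elevations plus rectified circular first differences (on/off edge
#' channels): the elementary processing assumed upstream of the mushroom
#' body. All channels are non-negative.
#'
#' @param view elevation vector from [render_panorama()].
#' @return numeric feature vector of length `3 * n_azimuth`.
#' @export
view_features <- function(view) {
  d <- view - c(view[-1], view[1])  # circular difference
  c(view, pmax(0, d), pmax(0, -d))
}

#' Advance the agent kinematics one step
#'
#' Heading updates by `turn_rate * dt` plus optional Gaussian motor noise
#' (per-step SD, so squared heading deviation grows as n * sd^2); position
#' advances `speed * dt` along the new heading. The arena edge is
#' reflective. Uses the ambient RNG.
#'
#' @param p a [pose()].
#' @param turn_rate radians per unit time (CCW positive).
#' @param speed ground speed (>= 0).
#' @param dt timestep.
#' @param motor_noise_sd per-step heading noise SD, radians.
#' @param arena_radius reflective boundary radius (Inf to disable).
#' @return the new [pose()].
#' @export
step_kinematics <- function(p, turn_rate = 0, speed = 1, dt = 0.1,
                            motor_noise_sd = 0, arena_radius = Inf) {
  stopifnot(speed >= 0)
  eps <- if (motor_noise_sd > 0) stats::rnorm(1L, 0, motor_noise_sd) else 0
  kappa <- wrap_angle(p$kappa + turn_rate * dt + eps)
  x <- p$x + speed * dt * cos(kappa)
  y <- p$y + speed * dt * sin(kappa)
  r <- sqrt(x^2 + y^2)
  if (is.finite(arena_radius) && r > arena_radius) {
    # reflect: fold the overshoot back inside and mirror the heading about
    # the boundary tangent
    x <- x * (2 * arena_radius - r) / r
    y <- y * (2 * arena_radius - r) / r
    kappa <- wrap_angle(2 * atan2(y, x) + pi - kappa)
  }
  pose(x, y, kappa)
}

#' Scripted learning walk around the nest
#'
#' A synthetic stand-in for recorded learning walks: the agent spirals
#' outward around the nest in expanding loops; at regularly spaced stations
#' it emits several poses with headings spanning nest-facing, nest-averted
#' and tangential directions, so both internal reward channels are exercised
#' during off-policy training. Covers all azimuthal sectors for
#' `n_loops >= 4`.
#'
#' @param world a world (its nest anchors the walk by default).
#' @param n_loops number of spiral loops.
#' @param max_radius outermost station radius (< arena radius).
#' @param seed walk seed.
#' @param stations_per_loop stations sampled per loop.
#' @param headings_per_station poses emitted per station.
#' @param center walk anchor; defaults to the nest (bees also perform such
#'   orientation flights at newly found food sources).
#' @return data.frame with columns `x`, `y`, `kappa`.
#' @export
scripted_learning_walk <- function(world, n_loops = 4L, max_radius = 10,
                                   seed = 1L, stations_per_loop = 36L,
                                   headings_per_station = 4L,
                                   center = NULL) {
  stopifnot(max_radius < world$arena_radius)
  center <- center %||% world$nest
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "learning_walk"))
  n_st <- n_loops * stations_per_loop
  t <- seq_len(n_st) / n_st
  phi <- 2 * pi * n_loops * t + stats::runif(1, 0, 2 * pi)
  rad <- max_radius * (0.15 + 0.85 * t)
  out <- vector("list", n_st)
  for (i in seq_len(n_st)) {
    x <- center[1] + rad[i] * cos(phi[i])
    y <- center[2] + rad[i] * sin(phi[i])
    to_nest <- atan2(center[2] - y, center[1] - x)
    base <- to_nest + 2 * pi * (seq_len(headings_per_station) - 1L) /
      headings_per_station
    kap <- wrap_angle(base + stats::runif(headings_per_station, -0.3, 0.3))
    out[[i]] <- data.frame(x = rep(x, length(kap)),
                           y = rep(y, length(kap)), kappa = kap)
  }
  do.call(rbind, out)
}

#' Sense the world: view plus external reward
#'
#' Returns the panoramic view at the pose together with the valence-split
#' external reward: `r_plus` is the magnitude of an active feeder whose
#' capture radius contains the pose (the feeder is then depleted if
#' depletable); `r_minus` comes from aversive zones (none by default).
#'
#' @param world a world.
#' @param p a [pose()].
#' @param n_azimuth azimuth bins for the view.
#' @return list `view`, `r_plus`, `r_minus`, `feeder` (index captured or
#'   NA), `world` (with depletion applied).
#' @export
sense_and_reward <- function(world, p, n_azimuth = 36L) {
  view <- render_panorama(world, p, n_azimuth)
  r_plus <- 0; fed <- NA_integer_
  f <- world$feeders
  if (!is.null(f) && nrow(f) > 0L) {
    d <- sqrt((f$x - p$x)^2 + (f$y - p$y)^2)
    hit <- which(d <= world$capture_radius & f$active)
    if (length(hit) > 0L) {
      fed <- hit[1L]
      r_plus <- f$magnitude[fed]
      if (f$depletable[fed]) world$feeders$active[fed] <- FALSE
    }
  }
  list(view = view, r_plus = r_plus, r_minus = 0, feeder = fed,
       world = world)
}

#' Push a pose out of any landmark it penetrates
#'
#' Simple collision resolution for closed-loop simulation: if the position
#' lies inside (or within `margin` of) a landmark cylinder it is moved
#' radially to the surface plus margin; the heading is unchanged.
#'
#' @param world a world.
#' @param p a [pose()].
#' @param margin clearance kept from the cylinder surface.
#' @return a collision-free [pose()].
#' @export
resolve_collision <- function(world, p, margin = 0.2) {
  lm <- world$landmarks
  if (is.null(lm) || nrow(lm) == 0L) return(p)
  # push out of the most-violating cylinder with an escalating margin so
  # overlapping cylinders cannot trap the pose in an oscillation
  for (pass in 1:50) {
    clear <- sqrt((p$x - lm$x)^2 + (p$y - lm$y)^2) - lm$radius
    i <- which.min(clear)
    if (clear[i] >= margin) break
    dx <- p$x - lm$x[i]; dy <- p$y - lm$y[i]
    d <- sqrt(dx^2 + dy^2)
    if (d < 1e-9) { dx <- 1; dy <- 0; d <- 1 }
    lim <- lm$radius[i] + margin + 0.05 * pass
    p <- pose(lm$x[i] + dx / d * lim, lm$y[i] + dy / d * lim, p$kappa)
  }
  p
}

#' Serialize / restore a world as JSON
#'
#' Round-trips exactly (full double precision).
#'
#' @param world a world.
#' @param path file path.
#' @return `world_to_json` returns the path invisibly; `world_from_json` the
#'   restored world.
#' @export
world_to_json <- function(world, path) {
  jsonlite::write_json(unclass(world), path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname world_to_json
#' @export
world_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$nest <- as.numeric(x$nest)
  structure(x, class = "world")
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("<world> preset '%s', seed %d: %d feeder(s), %d landmark(s), arena radius %g\n",
              x$preset, x$seed,
              if (is.null(x$feeders)) 0L else nrow(x$feeders),
              if (is.null(x$landmarks)) 0L else nrow(x$landmarks),
              x$arena_radius))
  invisible(x)
}
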