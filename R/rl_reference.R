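#' Tabular reinforcement-learning reference
#'
#' Textbook finite MDPs, value iteration, and tabular SARSA/Q-learning used
#' as independent ground truth for the mushroom-body circuit.
#'
#' @name rl_reference
NULL

#' Specify a finite Markov decision process
#'
#' @param transition `n_states x n_actions x n_states` array, `P[s, a, s']`;
#'   each `P[s, a, ]` must sum to 1.
#' @param reward `n_states x n_actions` table `R(s, a)`.
#' @param gamma discount factor in `[0, 1]`.
#' @param terminal logical mask of terminal states; terminal states are
#'   forced to self-loop with zero reward.
#' @param start integer vector of candidate start states (uniform).
#' @return an `mdp` object.
#' @export
mdp_spec <- function(transition, reward, gamma = 0.9, terminal = NULL,
                     start = NULL) {
  d <- dim(transition)
  stopifnot(length(d) == 3L, d[1] == d[3], nrow(reward) == d[1],
            ncol(reward) == d[2], gamma >= 0, gamma <= 1)
  n_s <- d[1]; n_a <- d[2]
  terminal <- terminal %||% rep(FALSE, n_s)
  sums <- apply(transition, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-12))
    stop("mdp_spec: each P(. | s, a) must sum to 1", call. = FALSE)
  for (s in which(terminal)) {
    transition[s, , ] <- 0
    transition[s, , s] <- 1
    reward[s, ] <- 0
  }
  structure(list(transition = transition, reward = reward, gamma = gamma,
                 terminal = terminal, n_states = n_s, n_actions = n_a,
                 start = start %||% which(!terminal)),
            class = "mdp")
}

#' SARSA temporal-difference error
#'
#' Delta = R + gamma * Q(s', a') - Q(s, a); a terminal successor contributes
#' Q = 0.
#'
#' @param q Q table (`n_states x n_actions`).
#' @param s,a current state and action indices.
#' @param r immediate reward.
#' @param s_next,a_next successor state and action.
#' @param gamma discount.
#' @param terminal_next is `s_next` terminal?
#' @return the scalar TD error.
#' @export
sarsa_delta <- function(q, s, a, r, s_next, a_next, gamma,
                        terminal_next = FALSE) {
  q_next <- if (terminal_next) 0 else q[s_next, a_next]
  r + gamma * q_next - q[s, a]
}

#' Q-learning temporal-difference error
#'
#' Delta = R + gamma * max_a Q(s', a) - Q(s, a).
#'
#' @inheritParams sarsa_delta
#' @return the scalar TD error.
#' @export
q_learning_delta <- function(q, s, a, r, s_next, gamma,
                             terminal_next = FALSE) {
  q_next <- if (terminal_next) 0 else max(q[s_next, ])
  r + gamma * q_next - q[s, a]
}

#' Value iteration
#'
#' Iterates the Bellman optimality operator until the sup-norm residual
#' drops below `tol`. Ties in the greedy policy break to the lowest index.
#'
#' @param mdp an [mdp_spec()].
#' @param tol Bellman residual tolerance.
#' @param max_iter iteration cap.
#' @return list `v` (optimal state values), `q` (optimal action values),
#'   `policy` (greedy action per state), `iterations`.
#' @export
value_iteration <- function(mdp, tol = 1e-10, max_iter = 100000L) {
  if (mdp$gamma >= 1 && !any(mdp$terminal))
    stop("value_iteration: gamma must be < 1 or terminals present",
         call. = FALSE)
  n_s <- mdp$n_states; n_a <- mdp$n_actions
  v <- numeric(n_s)
  # flatten P to (s*a) x s' for fast expectation
  pm <- matrix(aperm(mdp$transition, c(1, 2, 3)), n_s * n_a, n_s)
  rv <- as.numeric(mdp$reward)
  for (it in seq_len(max_iter)) {
    q <- matrix(rv + mdp$gamma * as.numeric(pm %*% v), n_s, n_a)
    q[mdp$terminal, ] <- 0
    v_new <- apply(q, 1, max)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  q <- matrix(rv + mdp$gamma * as.numeric(pm %*% v), n_s, n_a)
  q[mdp$terminal, ] <- 0
  list(v = v, q = q, policy = apply(q, 1, which.max), iterations = it)
}

#' Evaluate a fixed policy by iterative policy evaluation
#'
#' @param mdp an [mdp_spec()].
#' @param policy integer vector (deterministic) or `n_states x n_actions`
#'   probability matrix.
#' @param tol convergence tolerance.
#' @return state-value vector under the policy.
#' @export
policy_evaluation <- function(mdp, policy, tol = 1e-12) {
  n_s <- mdp$n_states; n_a <- mdp$n_actions
  if (is.vector(policy) && !is.matrix(policy)) {
    pm <- matrix(0, n_s, n_a)
    pm[cbind(seq_len(n_s), policy)] <- 1
    policy <- pm
  }
  v <- numeric(n_s)
  repeat {
    q <- sapply(seq_len(n_a), function(a)
      mdp$reward[, a] + mdp$gamma * mdp$transition[, a, ] %*% v)
    v_new <- rowSums(policy * q)
    v_new[mdp$terminal] <- 0
    if (max(abs(v_new - v)) < tol) return(as.numeric(v_new))
    v <- v_new
  }
}

# shared transition sampler
.mdp_step <- function(mdp, s, a) {
  p <- mdp$transition[s, a, ]
  s_next <- sample.int(mdp$n_states, 1L, prob = p)
  list(s_next = s_next, r = mdp$reward[s, a],
       terminal = mdp$terminal[s_next])
}

#' Run a tabular SARSA or Q-learning agent
#'
#' Episodic learning with epsilon-greedy or softmax exploration and an
#' exponential decay schedule `epsilon_k = epsilon0 * decay^k` per episode.
#' The update ordering matches the mushroom-body circuit step for step: at
#' arrival in a state the next action is chosen from the pre-update table,
#' the pending update is applied, and the post-update value is carried
#' forward as the high-latency trace.
#'
#' @param mdp an [mdp_spec()].
#' @param algo `"sarsa"` or `"q_learning"`.
#' @param alpha learning rate.
#' @param episodes number of episodes.
#' @param epsilon0 initial exploration rate.
#' @param decay per-episode exploration decay.
#' @param max_steps per-episode step cap.
#' @param seed RNG seed.
#' @param q0 initial Q value.
#' @return list `q` (final table), `policy` (greedy), `steps` (per-episode
#'   lengths), `deltas` (all TD errors in order).
#' @export
run_tabular_agent <- function(mdp, algo = c("sarsa", "q_learning"),
                              alpha = 0.1, episodes = 500L, epsilon0 = 0.2,
                              decay = 0.999, max_steps = 1000L, seed = 1L,
                              q0 = 0) {
  algo <- match.arg(algo)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  q <- matrix(q0, mdp$n_states, mdp$n_actions)
  steps <- integer(episodes)
  deltas <- numeric(0)
  for (ep in seq_len(episodes)) {
    eps <- epsilon0 * decay^(ep - 1L)
    s <- if (length(mdp$start) == 1L) mdp$start else
      sample(mdp$start, 1L)
    a <- select_action(q[s, ], "epsilon_greedy", epsilon = eps)
    for (t in seq_len(max_steps)) {
      tr <- .mdp_step(mdp, s, a)
      if (tr$terminal) {
        delta <- tr$r - q[s, a]
        q[s, a] <- q[s, a] + alpha * delta
        deltas <- c(deltas, delta)
        steps[ep] <- t
        break
      }
      a_next <- select_action(q[tr$s_next, ], "epsilon_greedy",
                              epsilon = eps)
      q_next <- if (algo == "sarsa") q[tr$s_next, a_next] else
        max(q[tr$s_next, ])
      delta <- tr$r + mdp$gamma * q_next - q[s, a]
      q[s, a] <- q[s, a] + alpha * delta
      deltas <- c(deltas, delta)
      s <- tr$s_next
      a <- a_next
      steps[ep] <- t
    }
  }
  list(q = q, policy = apply(q, 1, which.max), steps = steps, deltas = deltas)
}

#' Deterministic gridworld MDP
#'
#' Rectangular grid, actions (east, north, west, south); moves off the grid
#' stay in place. The goal state is terminal with entry reward `goal_reward`
#' and an optional per-step cost.
#'
#' @param nrow,ncol grid shape.
#' @param goal goal state index (default: last cell).
#' @param goal_reward reward on any transition out of a state into actions
#'   leading to the goal... the reward table is `R(s, a)`: entering the goal
#'   pays `goal_reward`.
#' @param step_cost constant added to every non-goal transition (<= 0 for a
#'   cost).
#' @param gamma discount.
#' @return an [mdp_spec()] with attribute `coords` (x, y per state).
#' @export
make_gridworld <- function(nrow = 5L, ncol = 5L, goal = nrow * ncol,
                           goal_reward = 1, step_cost = 0, gamma = 0.9) {
  n_s <- nrow * ncol; n_a <- 4L
  # state s -> (row r, col c), column-major
  rc <- cbind((seq_len(n_s) - 1L) %% nrow + 1L,
              (seq_len(n_s) - 1L) %/% nrow + 1L)
  moves <- rbind(c(0L, 1L), c(-1L, 0L), c(0L, -1L), c(1L, 0L))  # E N W S
  P <- array(0, c(n_s, n_a, n_s))
  R <- matrix(step_cost, n_s, n_a)
  for (s in seq_len(n_s)) {
    for (a in seq_len(n_a)) {
      r2 <- rc[s, 1] + moves[a, 1]; c2 <- rc[s, 2] + moves[a, 2]
      s2 <- if (r2 < 1 || r2 > nrow || c2 < 1 || c2 > ncol) s else
        (c2 - 1L) * nrow + r2
      P[s, a, s2] <- 1
      if (s2 == goal && s != goal) R[s, a] <- goal_reward
    }
  }
  term <- rep(FALSE, n_s); term[goal] <- TRUE
  m <- mdp_spec(P, R, gamma = gamma, terminal = term,
                start = setdiff(seq_len(n_s), goal))
  attr(m, "coords") <- rc
  m
}

#' Gradient-world MDP with visual-intensity features
#'
#' A virtual paradigm in which uniform visual intensity changes along a
#' predefined gradient as the agent walks: a 1D chain (actions left/right)
#' or a grid (4 actions) whose states carry scalar intensity features varying
#' monotonically along the gradient, optionally expanded into a coarse code
#' of Gaussian tuning-curve responses for population input to the mushroom
#' body. Reward is delivered at specific locations, which are absorbing.
#'
#' @param n_states chain length (1D), or use `shape = c(nrow, ncol)`.
#' @param shape optional grid shape; the gradient runs along the columns.
#' @param reward_states state indices delivering reward (terminal).
#' @param reward magnitude delivered at the reward states.
#' @param step_cost per-transition cost (<= 0).
#' @param gamma discount.
#' @param n_channels coarse-code channels; 1 returns the raw scalar feature.
#' @param tuning_sd tuning-curve width on the intensity axis.
#' @return list `mdp` ([mdp_spec()]) and `features`
#'   (`n_states x n_channels` matrix, strictly increasing intensity along
#'   the gradient).
#' @export
make_gradient_world <- function(n_states = 10L, shape = NULL,
                                reward_states = NULL, reward = 1,
                                step_cost = 0, gamma = 0.9,
                                n_channels = 1L, tuning_sd = 0.08) {
  if (is.null(shape)) {
    n_s <- n_states
    reward_states <- reward_states %||% n_s
    if (any(reward_states < 1 | reward_states > n_s))
      stop("make_gradient_world: reward state outside the chain",
           call. = FALSE)
    n_a <- 2L  # 1 = left (toward 1), 2 = right (toward n)
    P <- array(0, c(n_s, n_a, n_s))
    R <- matrix(step_cost, n_s, n_a)
    for (s in seq_len(n_s)) {
      s_left <- max(1L, s - 1L); s_right <- min(n_s, s + 1L)
      P[s, 1L, s_left] <- 1; P[s, 2L, s_right] <- 1
      if (s_left %in% reward_states && !(s %in% reward_states))
        R[s, 1L] <- reward + step_cost
      if (s_right %in% reward_states && !(s %in% reward_states))
        R[s, 2L] <- reward + step_cost
    }
    intensity <- seq(0, 1, length.out = n_s)
  } else {
    nr <- shape[1]; nc <- shape[2]
    base <- make_gridworld(nr, nc, goal = reward_states %||% (nr * nc),
                           goal_reward = reward, step_cost = step_cost,
                           gamma = gamma)
    reward_states <- reward_states %||% (nr * nc)
    if (any(reward_states < 1 | reward_states > nr * nc))
      stop("make_gradient_world: reward state outside grid", call. = FALSE)
    intensity <- (attr(base, "coords")[, 2] - 1) / max(1, nc - 1)
    feats <- .gradient_features(intensity, n_channels, tuning_sd)
    return(list(mdp = base, features = feats, intensity = intensity))
  }
  term <- rep(FALSE, n_s); term[reward_states] <- TRUE
  mdp <- mdp_spec(P, R, gamma = gamma, terminal = term,
                  start = setdiff(seq_len(n_s), reward_states))
  list(mdp = mdp,
       features = .gradient_features(intensity, n_channels, tuning_sd),
       intensity = intensity)
}

.gradient_features <- function(intensity, n_channels, tuning_sd) {
  if (n_channels <= 1L) return(matrix(intensity, ncol = 1L))
  centers <- seq(0, 1, length.out = n_channels)
  t(sapply(intensity, function(x) exp(-(x - centers)^2 / (2 * tuning_sd^2))))
}

#' Serialize / restore an MDP as JSON
#'
#' @param mdp an [mdp_spec()].
#' @param path file path.
#' @return `mdp_to_json` returns the path invisibly; `mdp_from_json` returns
#'   the reconstructed [mdp_spec()].
#' @export
mdp_to_json <- function(mdp, path) {
  jsonlite::write_json(list(
    transition = mdp$transition, reward = mdp$reward, gamma = mdp$gamma,
    terminal = mdp$terminal, start = mdp$start,
    dim = dim(mdp$transition)), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mdp_to_json
#' @export
mdp_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- array(as.numeric(x$transition), dim = x$dim)
  mdp_spec(tr, matrix(as.numeric(x$reward), x$dim[1], x$dim[2]),
           gamma = x$gamma, terminal = as.logical(x$terminal),
           start = as.integer(x$start))
}
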