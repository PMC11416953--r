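# Independent oracles and small generators used across the suite.

# complex-number representation of a phasor-decoded vector
decode_z <- function(p) {
  d <- phasor_decode(p)
  d$magnitude * exp(1i * d$angle)
}

# least-squares sinusoid fit (independent of the Fourier-projection decoder)
ls_sinusoid_fit <- function(rates, baseline, n_columns) {
  theta <- phasor_axes(n_columns)
  fit <- stats::lm((rates - baseline) ~ 0 + cos(theta) + sin(theta))
  a <- stats::coef(fit)[1]; b <- stats::coef(fit)[2]
  list(angle = atan2(b, a), magnitude = sqrt(a^2 + b^2))
}

# random finite MDP with row-stochastic transitions
random_mdp <- function(n_states, n_actions, gamma = 0.9, seed = 1) {
  set.seed(seed)
  P <- array(stats::rexp(n_states * n_actions * n_states),
             c(n_states, n_actions, n_states))
  for (s in seq_len(n_states)) for (a in seq_len(n_actions))
    P[s, a, ] <- P[s, a, ] / sum(P[s, a, ])
  R <- matrix(stats::rnorm(n_states * n_actions), n_states, n_actions)
  mdp_spec(P, R, gamma = gamma)
}

# policy iteration: an independent route to the optimal policy/values
policy_iteration_oracle <- function(mdp, tol = 1e-12) {
  policy <- rep(1L, mdp$n_states)
  repeat {
    v <- policy_evaluation(mdp, policy, tol = tol)
    q <- sapply(seq_len(mdp$n_actions), function(a)
      mdp$reward[, a] + mdp$gamma * mdp$transition[, a, ] %*% v)
    q[mdp$terminal, ] <- 0
    new_policy <- apply(q, 1, which.max)
    if (all(new_policy == policy)) return(list(v = v, policy = policy))
    policy <- new_policy
  }
}

# mirror a world about the x axis
mirror_world <- function(w) {
  if (!is.null(w$landmarks)) w$landmarks$y <- -w$landmarks$y
  if (!is.null(w$feeders)) w$feeders$y <- -w$feeders$y
  w
}

# the shared feeder layout used by the behavioural tests (nearest-neighbour
# order suboptimal; feeders well off each other's nest-anchored vectors)
trapline_world <- function(n_landmarks = 5L) {
  generate_world("traplining", seed = 1L,
                 config = list(feeder_positions = rbind(c(8, -2.5),
                                                        c(3.5, 9),
                                                        c(12, 10)),
                               n_landmarks = n_landmarks))
}
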