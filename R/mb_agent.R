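#' Run the mushroom-body TD circuit on a finite MDP
#'
#' Closes the state-action loop around the MB circuit: state features are
#' KC-encoded, MBON valence pairs read out Q, lateral inhibition (plus
#' exploration noise) selects the action, and the latency-split DAN signal
#' drives three-factor plasticity on the previous step's synapses. With
#' one-hot KC coding this is algebraically a tabular SARSA/Q-learning agent;
#' with population features it is a linear function approximator over the
#' KC code.
#'
#' @param mdp an [mdp_spec()].
#' @param features optional `n_states x n_pn` feature matrix; `NULL` uses
#'   one-hot (tabular) coding.
#' @param proj optional [kc_projection()]; defaults to identity for one-hot
#'   features or a random sparse projection otherwise.
#' @param f KC sparsity (ignored for one-hot coding).
#' @param n_kc Kenyon cells for the random projection.
#' @param algo `"sarsa"` (on-policy; default — the circuit reads out the
#'   experienced action) or `"q_learning"` (the low-latency pathway reads
#'   the greedy action's value).
#' @param alpha learning rate.
#' @param w0 baseline synaptic weight; must exceed the task's value range to
#'   avoid clipping.
#' @param episodes number of episodes.
#' @param epsilon0,decay epsilon-greedy exploration schedule (per episode).
#' @param max_steps per-episode step cap.
#' @param seed RNG seed (policy + environment draws).
#' @param record_stream also return the full transition stream for replay
#'   against a tabular oracle.
#' @return list with `mb` (final `mb_state`), `q_est` (probed
#'   `n_states x n_actions` Q table), `policy` (greedy), `clip_fraction`,
#'   and optionally `stream` (data.frame of s, a, r, s_next, a_next,
#'   terminal, delta, q_updated).
#' @export
run_mb_agent <- function(mdp, features = NULL, proj = NULL, f = 0.05,
                         n_kc = 500L, algo = c("sarsa", "q_learning"),
                         alpha = 0.1, w0 = 5, episodes = 200L,
                         epsilon0 = 0.2, decay = 0.999, max_steps = 500L,
                         seed = 1L, record_stream = FALSE) {
  algo <- match.arg(algo)
  n_s <- mdp$n_states; n_a <- mdp$n_actions
  if (is.null(features)) {
    features <- diag(n_s)
    proj <- proj %||% kc_projection_identity(n_s)
    f <- 1 / n_s
  } else {
    proj <- proj %||% kc_projection(ncol(features), n_kc,
                                    fan_in = max(2L, ncol(features) %/% 8L),
                                    seed = substream_seed(seed, "projection"))
  }
  kcs <- lapply(seq_len(n_s), function(s)
    kc_encode(features[s, ], proj, f))
  mb <- mb_state(proj$n_kc, n_a, w0 = w0, alpha = alpha, gamma = mdp$gamma)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "policy_env"))
  stream <- if (record_stream) vector("list", 0L) else NULL
  for (ep in seq_len(episodes)) {
    eps <- epsilon0 * decay^(ep - 1L)
    s <- if (length(mdp$start) == 1L) mdp$start else sample(mdp$start, 1L)
    qv <- q_forward(kcs[[s]], mb)
    a <- select_action(qv, "epsilon_greedy", epsilon = eps)
    ro <- mbon_readout(kcs[[s]], mb)
    trace <- trace_buffer(kcs[[s]], a, ro$q_plus[a], ro$q_minus[a])
    for (t in seq_len(max_steps)) {
      tr <- .mdp_step(mdp, s, a)
      r_plus <- max(tr$r, 0); r_minus <- max(-tr$r, 0)
      if (tr$terminal) {
        dan <- dan_td(r_plus, r_minus, 0, 0, trace, mdp$gamma)
        mb <- apply_plasticity(mb, trace, dan)
        if (record_stream)
          stream[[length(stream) + 1L]] <- data.frame(
            s = s, a = a, r = tr$r, s_next = tr$s_next, a_next = NA_integer_,
            terminal = TRUE, delta = dan$combined,
            q_updated = q_forward(kcs[[s]], mb)[a])
        break
      }
      s2 <- tr$s_next
      qv2 <- q_forward(kcs[[s2]], mb)               # pre-update readout
      a2 <- select_action(qv2, "epsilon_greedy", epsilon = eps)
      ro2 <- mbon_readout(kcs[[s2]], mb)
      a_val <- if (algo == "sarsa") a2 else which.max(qv2)
      dan <- dan_td(r_plus, r_minus, ro2$q_plus[a_val], ro2$q_minus[a_val],
                    trace, mdp$gamma)
      mb <- apply_plasticity(mb, trace, dan)
      ro2p <- mbon_readout(kcs[[s2]], mb)           # post-update trace copy
      if (record_stream)
        stream[[length(stream) + 1L]] <- data.frame(
          s = s, a = a, r = tr$r, s_next = s2, a_next = a2,
          terminal = FALSE, delta = dan$combined,
          q_updated = q_forward(kcs[[s]], mb)[a])
      trace <- trace_buffer(kcs[[s2]], a2, ro2p$q_plus[a2], ro2p$q_minus[a2])
      s <- s2; a <- a2
    }
  }
  q_est <- t(vapply(kcs, function(kc) q_forward(kc, mb), numeric(n_a)))
  out <- list(mb = mb, q_est = q_est,
              policy = apply(q_est, 1, which.max),
              clip_fraction = mb_clip_fraction(mb, warn = TRUE))
  if (record_stream) out$stream <- do.call(rbind, stream)
  out
}

#' Replay a transition stream through the tabular TD rule
#'
#' The independent oracle for circuit equivalence: applies the textbook
#' SARSA or Q-learning update to the exact experience stream recorded from
#' [run_mb_agent()] and returns the per-step updated values and final table.
#'
#' @param stream data.frame from `run_mb_agent(..., record_stream = TRUE)`.
#' @param n_states,n_actions table shape.
#' @param alpha learning rate.
#' @param gamma discount.
#' @param algo `"sarsa"` or `"q_learning"`.
#' @return list `q` (final table), `deltas`, `q_updated` (value of the
#'   updated entry after each step).
#' @export
replay_tabular <- function(stream, n_states, n_actions, alpha, gamma,
                           algo = c("sarsa", "q_learning")) {
  algo <- match.arg(algo)
  q <- matrix(0, n_states, n_actions)
  n <- nrow(stream)
  deltas <- numeric(n); q_upd <- numeric(n)
  for (i in seq_len(n)) {
    s <- stream$s[i]; a <- stream$a[i]; r <- stream$r[i]
    delta <- if (stream$terminal[i]) {
      r - q[s, a]
    } else if (algo == "sarsa") {
      sarsa_delta(q, s, a, r, stream$s_next[i], stream$a_next[i], gamma)
    } else {
      q_learning_delta(q, s, a, r, stream$s_next[i], gamma)
    }
    q[s, a] <- q[s, a] + alpha * delta
    deltas[i] <- delta; q_upd[i] <- q[s, a]
  }
  list(q = q, deltas = deltas, q_updated = q_upd)
}

#' Mushroom-body conditioning (Rescorla-Wagner / direct modes)
#'
#' Repeated stimulus-reward pairing with the RPE or direct-reinforcement DAN
#' wiring, applied to the *current* step's synapses (no temporal link). With
#' the RPE wiring the prediction error of a fixed pairing decays as
#' `(1 - alpha)^n`; removing the reward extinguishes the prediction without
#' negative weights.
#'
#' @param mb an `mb_state` (single action is typical).
#' @param kc the stimulus `kc_activation`.
#' @param r_plus,r_minus reward pairing per trial (scalars or length-n
#'   vectors for schedules).
#' @param trials number of pairings.
#' @param mode `"rpe"` or `"direct"`.
#' @param action stimulated action index.
#' @return list `mb`, `errors` (combined DAN signal per trial), `q` (value
#'   trajectory after each trial).
#' @export
run_mb_conditioning <- function(mb, kc, r_plus, r_minus = 0, trials = 20L,
                                mode = c("rpe", "direct"), action = 1L) {
  mode <- match.arg(mode)
  rp <- rep_len(r_plus, trials); rm <- rep_len(r_minus, trials)
  errors <- numeric(trials); qtraj <- numeric(trials)
  for (i in seq_len(trials)) {
    ro <- mbon_readout(kc, mb)
    dan <- if (mode == "rpe")
      dan_rpe(rp[i], rm[i], ro$q_plus[action], ro$q_minus[action])
    else dan_direct(rp[i], rm[i])
    mb <- apply_plasticity(mb, trace_buffer(kc, action, ro$q_plus[action],
                                            ro$q_minus[action]), dan)
    errors[i] <- dan$combined
    qtraj[i] <- q_forward(kc, mb)[action]
  }
  list(mb = mb, errors = errors, q = qtraj)
}
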