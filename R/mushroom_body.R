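#' The mushroom-body learning circuit
#'
#' Sensory input (projection-neuron features) is recoded by a fixed, sparse,
#' random projection onto Kenyon cells (KCs); a k-winners-take-all threshold
#' yields a sparse binary state representation. KCs synapse onto valence
#' pairs of mushroom-body output neurons (MBONs): for each discrete action i,
#' an appetitive and an aversive MBON whose rate difference is read as the
#' action value Q(s, a_i). Dopaminergic neurons (DANs) gate a depressive
#' three-factor plasticity rule at the KC-to-MBON synapse; depending on the
#' recurrent MBON-to-DAN wiring, the DAN population signal is the direct
#' reinforcement R, a Rescorla-Wagner reward-prediction error, or (with a
#' latency-split recurrence carrying a one-step activity trace) the full
#' SARSA temporal-difference error.
#'
#' @name mushroom_body
NULL

#' Fixed sparse random PN-to-KC projection
#'
#' Each KC receives exactly `fan_in` presynaptic projection-neuron inputs,
#' chosen uniformly at random; the wiring is non-plastic after construction.
#'
#' @param n_pn number of projection-neuron inputs.
#' @param n_kc number of Kenyon cells.
#' @param fan_in synapses per KC (<= n_pn).
#' @param seed wiring seed.
#' @return a `kc_projection` object holding a binary `n_pn x n_kc` matrix.
#' @export
kc_projection <- function(n_pn, n_kc, fan_in = min(8L, n_pn), seed = 1L) {
  stopifnot(fan_in >= 1L, fan_in <= n_pn)
  w <- matrix(0, n_pn, n_kc)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (j in seq_len(n_kc)) w[sample.int(n_pn, fan_in), j] <- 1
  structure(list(weights = w, n_pn = n_pn, n_kc = n_kc,
                 fan_in = fan_in, seed = seed),
            class = "kc_projection")
}

#' Identity projection for one-hot (tabular) KC coding
#'
#' With one KC per state and sparsity 1/n_kc, the MB circuit reduces exactly
#' to a tabular learner; used for oracle-equivalence checks.
#'
#' @param n_states number of states (= n_pn = n_kc).
#' @return a `kc_projection` with identity weights.
#' @export
kc_projection_identity <- function(n_states) {
  structure(list(weights = diag(n_states), n_pn = n_states,
                 n_kc = n_states, fan_in = 1L, seed = NA_integer_),
            class = "kc_projection")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sparse KC activation by k-winners-take-all
#'
#' KC drive is the projection of the feature vector; the top
#' `ceiling(f * n_kc)` cells by drive are active, ties broken by lowest
#' index. An all-zero feature vector yields a flagged all-zero activation on
#' which no learning is applied.
#'
#' @param features numeric PN feature vector (length n_pn).
#' @param proj a [kc_projection()].
#' @param f target sparsity fraction (default 0.05).
#' @return a `kc_activation`: list with `idx` (active indices), `k`, `n_kc`,
#'   `zero` flag.
#' @export
kc_encode <- function(features, proj, f = 0.05) {
  stopifnot(length(features) == proj$n_pn)
  if (all(features == 0))
    return(structure(list(idx = integer(0), k = 0L, n_kc = proj$n_kc,
                          zero = TRUE), class = "kc_activation"))
  drive <- as.numeric(crossprod(proj$weights, features))
  k <- as.integer(ceiling(f * proj$n_kc))
  idx <- order(-drive, seq_along(drive))[seq_len(k)]
  structure(list(idx = sort(idx), k = k, n_kc = proj$n_kc, zero = FALSE),
            class = "kc_activation")
}

#' Mushroom-body synaptic state (the Q estimate)
#'
#' Holds the non-negative KC-to-MBON weight matrices for the appetitive
#' (`w_plus`) and aversive (`w_minus`) MBON sets. Both start at the uniform
#' baseline `w0`, so all value predictions are zero before learning. Because
#' plasticity is depression-only, representable Q values are confined to
#' `[-w0, w0]`; size `w0` to the task's value range so updates never clip.
#'
#' @param n_kc number of Kenyon cells.
#' @param n_actions number of MBON valence pairs (discrete actions).
#' @param w0 baseline initial weight.
#' @param alpha learning rate in `[0, 1]`.
#' @param gamma temporal discount in `[0, 1]`.
#' @return an `mb_state` object.
#' @export
mb_state <- function(n_kc, n_actions, w0 = 0.5, alpha = 0.1, gamma = 0.9) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1, w0 >= 0)
  structure(list(
    w_plus = matrix(w0, n_kc, n_actions),
    w_minus = matrix(w0, n_kc, n_actions),
    n_kc = n_kc, n_actions = n_actions, w0 = w0,
    alpha = alpha, gamma = gamma,
    n_updates = 0L, n_clipped = 0L), class = "mb_state")
}

#' Valence-resolved MBON readout
#'
#' M+/- (i) = w+/-[, i] . kc / k: the mean synaptic weight over active KCs,
#' per action and valence.
#'
#' @param kc a `kc_activation`.
#' @param mb an `mb_state`.
#' @return list `q_plus`, `q_minus` (numeric vectors over actions).
#' @export
mbon_readout <- function(kc, mb) {
  if (kc$zero || kc$k == 0L)
    return(list(q_plus = numeric(mb$n_actions),
                q_minus = numeric(mb$n_actions)))
  list(
    q_plus = colSums(mb$w_plus[kc$idx, , drop = FALSE]) / kc$k,
    q_minus = colSums(mb$w_minus[kc$idx, , drop = FALSE]) / kc$k)
}

#' Action values from MBON activity
#'
#' Q(s, a_i) = M+(i) - M-(i). Equal baselines imply Q = 0 before learning.
#'
#' @inheritParams mbon_readout
#' @return numeric vector of Q values over actions.
#' @export
q_forward <- function(kc, mb) {
  r <- mbon_readout(kc, mb)
  r$q_plus - r$q_minus
}

#' Select an action from Q values
#'
#' Greedy selection corresponds to winner-take-all lateral inhibition between
#' MBONs; epsilon-greedy and softmax model circuit noise. Ties break to the
#' lowest index. Uses the ambient RNG.
#'
#' @param q numeric vector of action values.
#' @param policy `"greedy"`, `"epsilon_greedy"` or `"softmax"`.
#' @param epsilon exploration rate for epsilon-greedy, in `[0, 1]`.
#' @param beta inverse temperature (>= 0) for softmax.
#' @return selected action index (1-based).
#' @export
select_action <- function(q, policy = c("greedy", "epsilon_greedy", "softmax"),
                          epsilon = 0.1, beta = 1) {
  policy <- match.arg(policy)
  stopifnot(length(q) >= 1L)
  greedy <- which.max(q)  # which.max takes the lowest index on ties
  switch(policy,
    greedy = greedy,
    epsilon_greedy = {
      if (epsilon < 0 || epsilon > 1)
        stop("select_action: epsilon must lie in [0, 1]", call. = FALSE)
      if (stats::runif(1L) < epsilon) sample.int(length(q), 1L) else greedy
    },
    softmax = {
      if (beta < 0)
        stop("select_action: beta must be >= 0", call. = FALSE)
      z <- beta * (q - max(q))
      p <- exp(z) / sum(exp(z))
      sample.int(length(q), 1L, prob = p)
    })
}

#' DAN signal: direct reinforcement
#'
#' The canonical circuit: appetitive/aversive DANs relay the valence-split
#' external reward, D = R+ - R-.
#'
#' @param r_plus,r_minus non-negative reward components.
#' @return a `dan_signal`: list `d_plus`, `d_minus`, `combined`.
#' @export
dan_direct <- function(r_plus, r_minus = 0) {
  if (r_plus < 0 || r_minus < 0)
    stop("dan_direct: rewards must arrive valence-split (non-negative)",
         call. = FALSE)
  list(d_plus = r_plus, d_minus = r_minus, combined = r_plus - r_minus)
}

#' DAN signal: reward-prediction error via cross-valence recurrence
#'
#' Excitatory MBON-to-DAN feedback of opposite valence adds the prediction of
#' negative reward to the appetitive DAN and vice versa, so the DAN
#' population difference is the full Rescorla-Wagner prediction error:
#' D = (R+ + Q-) - (R- + Q+) = R - Q.
#'
#' @param r_plus,r_minus non-negative reward components.
#' @param q_plus,q_minus current valence-specific predictions (>= 0).
#' @return a `dan_signal`.
#' @export
dan_rpe <- function(r_plus, r_minus, q_plus, q_minus) {
  stopifnot(r_plus >= 0, r_minus >= 0)
  d_plus <- r_plus + q_minus
  d_minus <- r_minus + q_plus
  list(d_plus = d_plus, d_minus = d_minus, combined = d_plus - d_minus)
}

#' One-step MBON activity trace
#'
#' The high-latency recurrent pathway carries the previous step's KC pattern,
#' selected action, and valence-specific value readouts.
#'
#' @param kc `kc_activation` at the previous step.
#' @param action previously selected action index.
#' @param q_plus,q_minus valence readouts of the previous state-action pair.
#' @return a `trace_buffer`.
#' @export
trace_buffer <- function(kc, action, q_plus, q_minus) {
  list(kc = kc, action = action, q_plus = q_plus, q_minus = q_minus)
}

#' DAN signal: latency-split temporal-difference error
#'
#' Low-latency, equal-valence MBON-to-DAN recurrence (gain gamma) conveys the
#' current state-action prediction; high-latency, cross-valence recurrence
#' conveys the previous step's. The DAN population difference is then exactly
#' the SARSA TD error:
#' D = (R+ - R-) + gamma (Q+ - Q-)(t) - (Q+ - Q-)(t') = R + gamma Q(t) - Q(t').
#' gamma sits on the low-latency (current-value) pathway; this is the only
#' placement that reduces to the SARSA error for every gamma.
#'
#' @param r_plus,r_minus non-negative reward components at arrival.
#' @param q_plus_now,q_minus_now valence readouts of the current state-action
#'   pair (0 at a terminal state).
#' @param trace a [trace_buffer()] from the previous step; if `NULL` (episode
#'   start) there is no DAN output and no update.
#' @param gamma temporal discount.
#' @return a `dan_signal`, or `NULL` when the trace is empty.
#' @export
dan_td <- function(r_plus, r_minus, q_plus_now, q_minus_now, trace, gamma) {
  if (is.null(trace)) return(NULL)
  stopifnot(r_plus >= 0, r_minus >= 0)
  d_plus <- r_plus + gamma * q_plus_now + trace$q_minus
  d_minus <- r_minus + gamma * q_minus_now + trace$q_plus
  list(d_plus = d_plus, d_minus = d_minus, combined = d_plus - d_minus)
}

#' Apply DAN-gated three-factor plasticity
#'
#' Only synapses from the trace's active KCs onto the trace's selected
#' action's MBON pair change. The rule is depressive and cross-valence, and
#' it is gated by the *differential* DAN drive (the two DAN populations
#' compete at the synapse): an appetitive DAN excess `D = d_plus - d_minus
#' > 0` depresses the aversive pathway by `alpha * D` per active synapse,
#' an aversive excess depresses the appetitive pathway, and balanced DAN
#' activity leaves the weights unchanged. With the k-normalised MBON
#' readout this changes Q(s, a) by exactly `alpha * combined` whenever no
#' weight clips at zero, i.e. whenever Q stays within `[-w0, w0]`. Clipping
#' events are counted on the state.
#'
#' @param mb an `mb_state`.
#' @param trace a [trace_buffer()] naming the synapses to update (for the
#'   RPE/direct modes, pass a trace built from the *current* step).
#' @param dan a DAN signal.
#' @return the updated `mb_state`.
#' @export
apply_plasticity <- function(mb, trace, dan) {
  if (is.null(trace) || is.null(dan)) return(mb)
  idx <- trace$kc$idx
  if (length(idx) == 0L) return(mb)
  a <- trace$action
  net <- dan$d_plus - dan$d_minus
  clipped <- 0L
  if (net > 0) {
    new_minus <- mb$w_minus[idx, a] - mb$alpha * net
    clipped <- sum(new_minus < 0)
    mb$w_minus[idx, a] <- pmax(0, new_minus)
  } else if (net < 0) {
    new_plus <- mb$w_plus[idx, a] + mb$alpha * net
    clipped <- sum(new_plus < 0)
    mb$w_plus[idx, a] <- pmax(0, new_plus)
  }
  mb$n_updates <- mb$n_updates + 1L
  mb$n_clipped <- mb$n_clipped + as.integer(clipped > 0)
  mb
}

#' Fraction of updates that hit the zero-weight clip
#'
#' A run where more than 1% of updates clip indicates the baseline weight
#' `w0` is too small for the task's value range.
#'
#' @param mb an `mb_state`.
#' @param warn emit the saturation warning when above 1%.
#' @return the clip fraction.
#' @export
mb_clip_fraction <- function(mb, warn = TRUE) {
  frac <- if (mb$n_updates == 0L) 0 else mb$n_clipped / mb$n_updates
  if (warn && frac > 0.01)
    warning(sprintf(
      "mushroom body: %.1f%% of plasticity updates clipped at zero; increase w0",
      100 * frac), call. = FALSE)
  frac
}
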