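---
title: "An insect mushroom-body / central-complex reinforcement-learning navigation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An insect mushroom-body / central-complex reinforcement-learning navigation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeline)
```

`beeline` simulates a hypothesis about how central-place foraging insects
(bees, ants) could implement reinforcement learning with the circuitry of
their central complex (CX) and mushroom bodies (MB). This vignette is the
package's own account of the model: the assumptions it makes, the
parameters that matter, the design decisions that were genuinely open, and
what the simulations do and do not show.

## The phasor code and the central complex

All 2D vectors in the model live in a *phasor* population code: a vector
with angle $\theta$ and length $m$ is the activity profile
$r_i = b + m\cos(\theta - \theta_i)$ across $N$ columnar units with evenly
spaced preferred directions $\theta_i = 2\pi i/N$ and a baseline rate $b$.
The default $N = 8$ matches the eight columnar compartments per hemisphere
of the insect protocerebral bridge, spaced $360/8 = 45^\circ$ apart. The
code is closed under vector addition (element-wise rate addition minus one
baseline), which is all the CX needs:

* **Heading (TB1-like).** A unit-magnitude phasor at the current heading
  $\kappa$. The sky compass is treated as given: ground truth plus optional
  Gaussian noise, no ring-attractor dynamics.
* **Travel direction.** The heading phasor rotated by the egocentric
  optic-flow direction and scaled by ground speed, so sideways drift is
  integrated correctly.
* **Path integration (CPU4-like).** The travel phasor accumulates into a
  home vector storing the *nest-to-agent* displacement; the homing drive is
  its negation, which makes "zero at the nest" literal. Exceeding the
  representable length (the phasor baseline, default 1000 arena units)
  raises a saturation error rather than silently clipping.
* **Vector memories.** Storing a memory writes the negative imprint of the
  current CPU4 snapshot into a weight vector. Replaying the imprint against
  the current home vector $h$ yields the phasor of $m - h$: the direct
  shortcut from wherever the agent is to the remembered location. There is
  no eviction: storing beyond capacity is an error, because no biological
  mechanism for re-assigning memories is assumed.
* **Internal left/right reward.** The comparator computes
  $\delta = \mathrm{wrap}(\angle(m - h) - \kappa)$; in binary mode the left
  channel fires if $\delta > 0$ (goal to the left, counter-clockwise), in
  graded mode the channels carry $\max(0, \pm\sin\delta)$. A goal dead
  ahead or dead behind yields no reward on either channel.

Angles are radians, counter-clockwise positive, $0$ = allocentric $+x$;
this single convention is used by every module.

## The mushroom body as a value learner

Sensory input (projection-neuron features) is recoded by a fixed sparse
random projection onto Kenyon cells (KCs); a $k$-winners-take-all threshold
(default sparsity $f = 0.05$) yields the state code. For each discrete
action $a_i$ a *valence pair* of MB output neurons (MBONs) reads the KC
code through plastic synapses $w_\pm$, both initialised at a baseline
$w_0$; the action value is read out as
$Q(s, a_i) = (w_+ - w_-)\cdot\mathrm{kc}/k$. Action selection is
winner-take-all lateral inhibition (greedy), optionally softened into
$\epsilon$-greedy or softmax selection to model circuit noise.

The dopaminergic (DAN) population signal depends on the recurrent
MBON-to-DAN wiring:

* **Direct reinforcement:** $D = R_+ - R_-$ (the canonical conditioning
  circuit).
* **Reward-prediction error:** cross-valence excitatory feedback adds the
  opposite prediction to each DAN channel, so
  $D = (R_+ + Q_-) - (R_- + Q_+) = R - Q$, the Rescorla–Wagner error.
  Under a fixed pairing the error decays exactly as $(1-\alpha)^n$, and
  extinction drives the prediction back to zero without negative weights.
* **Temporal-difference error:** a *latency split* — low-latency
  equal-valence feedback carrying the current state–action prediction with
  gain $\gamma$, plus high-latency cross-valence feedback carrying a
  one-timestep activity trace — makes the DAN difference exactly the SARSA
  error $R + \gamma Q(s', a') - Q(s, a)$. The latencies are realised as a
  one-step buffer; placing $\gamma$ on the low-latency (current-value)
  pathway is the only arrangement that reduces to the SARSA error for all
  $\gamma$. An off-policy variant reads the greedy action's value instead
  (Q-learning).

**Plasticity.** The three-factor rule depresses only synapses from the
previously active KCs onto the previously selected action's MBON pair, and
it is gated by the *differential* DAN drive: an appetitive excess
depresses the aversive pathway by $\alpha(D_+ - D_-)$ per synapse and vice
versa, so balanced DAN activity leaves weights unchanged. We considered
applying the two DAN channels independently, but that rule has no stable
non-zero fixed point: each channel's drive contains the absolute MBON
rates, so both weight matrices decay by their common mode within a few
visits regardless of $w_0$. Opponent competition between the DAN channels
at the synapse restores exact tabular semantics: every update changes
$Q(s, a)$ by $\alpha\,\delta$ whenever no weight clips at zero. Because
depression is the only primitive, representable values are confined to
$[-w_0, w_0]$ and every sign reversal of the error consumes baseline-weight
"credit"; long runs therefore need $w_0$ several times the task's value
range (the equivalence runs use $w_0 = 20$), and the clip counter warns
when more than 1% of updates saturate.

With one-hot KC coding the circuit *is* tabular SARSA, and the test suite
holds it to the textbook update at $10^{-12}$ over a 5,000-step gridworld
run, with the circuit's update ordering (select next action from the
pre-update readout, apply the pending update, carry the post-update value
as the high-latency trace) mirrored exactly in the tabular oracle.

## Visual homing with internal rewards

The steering controller is two hemispheric copies of the conditioning
circuit. Both hemispheres receive copies of the CX left/right reward;
within each, the left reward reinforces the steer-left MBON by depressing
the steer-right pathway and vice versa; ipsilateral integration inverts
sign between hemispheres, so the hemibrains emit competing steer-left and
steer-right commands and the net turn is their difference times a premotor
gain, clipped at `max_turn`. The right hemisphere's PN-to-KC wiring is the
left's composed with the visual-field mirror (the hemibrains are
anatomical mirror images), which makes the whole controller exactly
equivariant under world mirroring — the test suite checks this up to
floating-point summation order in the winner-take-all.

Training is off-policy and associative (no prediction error): the agent is
driven along scripted learning walks — expanding loops with stations that
sample several headings, so both reward channels are exercised — while
dense internal rewards reinforce view–steering associations. Because the
learning rule is purely correlational, each KC effectively integrates the
signed left/right exposure of the views it responds to. Two consequences
shaped the design:

* **Synaptic homeostasis.** Subtractive depression ratchets both steering
  pathways to zero under continual learning. The steering update is
  therefore multiplicative with pairwise rescaling back to the baseline
  (synaptic scaling), which turns each synapse pair into a bounded
  integrator of signed exposure that stays informative indefinitely.
* **Goal-anchored visual structure.** A correlational learner can only
  associate views with "goal left/right" if some view feature correlates
  with goal side. The world presets therefore mark salient locations with
  beacons — a tower on the nest, a distinctively sized tower beside each
  feeder — the classic cylinder-array arrangement of insect homing
  experiments. In featureless or uniformly cluttered scenes the signal is
  genuinely unlearnable by this rule, which we regard as a property of the
  model, not a defect of the implementation.

Steering accuracy is modest (the packaged checks require sign agreement
with the comparator on at least 70% of familiar poses and closed-loop
visual homing on at least half of trials, against an untrained baseline
near zero). `steer_scan()` additionally exposes scanning: sampling the
signed drive over evenly spaced headings and decoding its first harmonic
estimates the goal bearing, coherently averaging the noise of individual
views.

## The hierarchical agent

The full agent closes the loop: a meta-controller (an MB TD circuit whose
actions are the stored vector memories plus "home") selects navigational
sub-goals from the current panorama under external reward; path
integration or the visual steering circuits execute the leg; and every
memory's steering circuit keeps learning off-policy from its own internal
reward at every step, whichever goal is active.

Decisions fire at bout start, on sub-goal capture, and on timeout
(semi-MDP); the external reward accumulated between decisions — minus a
metabolic travel cost per distance unit — is the meta-reward, undiscounted
within a segment with $\gamma$ applied per decision. Without some travel
cost every feeder order would earn the same return and no route could ever
be preferred; the cost (default 0.05 reward per arena unit against feeder
rewards of 1) is what makes shorter routes pay. Choices we fixed after the
design proved them necessary:

* **Compass-aligned meta view.** The meta-state is the KC code of the
  panorama rendered at compass heading zero (gaze stabilisation at decision
  points). The raw egocentric view confounds place with heading, which
  would make sub-goal choice depend on arrival direction.
* **No self-targets.** A memory whose location the agent is standing on is
  masked from selection; otherwise the zero-cost self-loop traps the greedy
  policy.
* **Landing.** Sensing food pulls the agent onto the feeder (path
  integration tracks the landing move), so stored vectors point at the
  feeder itself rather than at the rim of its sensing radius — without
  this, goal arrivals systematically miss the reward radius and the policy
  collapses.
* **Crop capacity.** An optional crop limit ends foraging (forces the
  homing motivation) once enough reward is collected; the shortcut
  experiment uses a one-feeder crop, as in nectar foraging.
* **Pre-training.** Experiments begin with a guided visit to each feeder
  (as animals are pre-trained in flight-cage studies), storing one vector
  memory per feeder one-shot at the rewarded location, followed by
  orientation walks around the nest and each feeder during which all
  steering slots learn concurrently.
* **Discount and determinism.** $\gamma = 0.6$ per decision keeps the
  negative tails of depleted-feeder visits (the view state does not encode
  depletion — deliberate, the meta-state is vision only) from drowning the
  reward signal; the softmax inverse temperature ramps by 2% per bout, the
  "determinism parameter" that moves the agent from exploratory to
  exploitative bouts.

**MBON budget.** Each memorised location costs three MBONs per hemisphere
(one selection, two steering); `mbon_budget()` validates the total against
the ~200-MBON-per-hemisphere budget of a honeybee, so at most 66 locations
fit.

## Experiments and what they show

All experiments are seeded simulation protocols on generated worlds; no
external data are used.

* **Traplining** (`run_traplining_experiment`): repeated bouts on a
  replenishing 3-feeder world whose layout makes the nearest-neighbour
  order 13% longer than the optimal tour, with every feeder several
  capture radii off the nest-anchored vector of its optimal-route
  successor. The logged asymptotic order-implied tour length (we compare
  orders by their Euclidean tour length, since realised paths carry motor
  jitter that affects all orders alike) must not exceed the
  nearest-neighbour baseline, and the per-bout tour length trends
  downward — route consolidation is gradual, not stepwise.
* **Displacement** (`run_displacement_test`): a trained agent is placed at
  a route feeder with a zeroed home vector and must continue the route on
  vision alone (meta decisions from the view, visual steering, up to three
  legs). The comparison is directional: the visual agent's next-feeder
  capture rate must exceed both a vector-sequence agent (which replays the
  correct stored vector from the wrong origin) and a random-heading
  flight. The visual channel is weak in absolute terms; the claim tested
  is only that view-based selection plus steering carries information the
  vector replay cannot.
* **Shortcut** (`run_shortcut_test`): after training with a near feeder C
  and a far feeder B under a one-feeder crop, C is permanently depleted.
  The greedy choice probed at the nest must switch to B within the bout
  budget (it typically takes a handful of bouts, by TD re-pricing of C),
  the first post-depletion B-leg typically departs from C's location —
  a transit never travelled before (the novel-route flag) — and a control
  run without depletion must not switch.

Problem sizes (12-state gradient worlds, 5×5 gridworlds, 3-feeder arenas,
20 seeds, a few hundred KCs) were chosen so the full suite runs on a
laptop in minutes; all thresholds are stated in the tests themselves.

## What the generator does not emulate

The worlds are flat, noise-free skylines of opaque cylinders with
deterministic geometry; real panoramas have texture, depth cues, lighting
and clutter, and real compasses and odometers drift in correlated ways.
Passing these simulations therefore shows that the *circuitry* can carry
the claimed computations under the stated coding assumptions — not that
the visual front end would survive natural scenes. Other known
limitations, inherited from the model rather than the code: a single
behavioural mode (no separate learning/foraging flight programs), no
eviction or decay of vector memories, vision as the only sensory modality,
and an associative (not error-corrective) steering learner whose accuracy
is bounded by the label coherence of the KC code.
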