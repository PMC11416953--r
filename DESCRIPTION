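Package: beeline
Title: Insect Mushroom-Body and Central-Complex Reinforcement-Learning
    Navigation Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a neuroanatomically inspired reinforcement-learning
    architecture for central-place foraging insects. The central complex is
    modelled as a phasor (sinusoidal population) code supporting heading
    representation, path integration, vector memories and shortcut vectors;
    the mushroom body as a sparse Kenyon-cell expansion with valence-paired
    output neurons whose dopaminergic feedback implements direct
    reinforcement, reward-prediction errors, or a latency-split
    temporal-difference (SARSA/Q-learning) error. A double-opponent,
    two-hemisphere visual steering circuit learns homing from internal
    left/right rewards, and a hierarchical meta-controller learns a policy
    over stored vector memories from external reward. Includes tabular RL
    oracles, seeded 2D foraging worlds with panoramic skyline rendering, and
    simulation protocols for traplining, displacement and shortcut
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
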