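Package: metadyna
Title: Meta-Control Reinforcement Learning with Mental Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements Meta-Dyna, a Dyna-style reinforcement-learning agent
    that arbitrates between model-based and model-free control using the
    reliability of their respective prediction errors, and trains its
    model-based values by mental simulation (rollouts) from a learned world
    model (tabular transition counts or a recurrent mixture-density network).
    Ships three stochastic benchmark environments (a two-stage Markov decision
    task, a local-change-adaptation gridworld, and a single-point Pong
    variant), baseline agents (Q-learning, SARSA, FORWARD, Dyna-Q, DQN and
    hybrid arbitration agents), evaluation metrics (mean normalized reward,
    choice optimality, trials-for-success), multi-seed experiment presets and
    a command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
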