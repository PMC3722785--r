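Package: cogseq
Title: Neural-Circuit Simulation of Strategic Cognitive Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulations of four neural-circuit models of how the
    prefrontal cortex, basal ganglia, dopamine system and hippocampus
    cooperate to select and sequence cognitive actions. Provides a minimal
    rate-coded network substrate (k-winners-take-all inhibition, bidirectional
    attractor settling, Hebbian, contrastive error-driven and
    dopamine-modulated three-factor learning), a delta-rule dopamine critic
    with effort-discounted bursts, basal-ganglia style Go/NoGo gating of
    working-memory stripes, and four ready-to-run experiments: model-free
    reinforcement learning of room-navigation action sequences, reward/effort
    based strategy selection with orbitofrontal and cingulate running-average
    value stripes, one-shot hippocampal instructed learning of if-then rules,
    and constraint-satisfaction discovery of bridging subgoal states. All
    inputs are synthetic and seeded; experiment results are returned as tidy
    tibbles with broom-style tidiers and ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
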