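Package: stairgait
Title: Muscle-Driven Simulation of Stair and Ramp Ascent Learned with
    Proximal Policy Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Forward dynamics of a planar muscle-driven human model with
    Hill-type muscles and first-order excitation-activation dynamics,
    elastic-foundation foot-ground contact against watertight triangulated
    stair and ramp meshes, a synthetic reference-gait generator with
    TRC/CSV trajectory readers, an imitation-plus-goal reward, proximal
    policy optimization of a binary muscle-excitation policy, and gait
    evaluation metrics (joint-angle correlations, reward fractions, muscle
    force summaries, and ground-reaction-force reports at the center of
    pressure).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
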