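Package: stsbalance
Title: Sit-to-Stand Balance Feasibility Maps from Inverted-Pendulum Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts sagittal-plane balance controllability of sit-to-stand
    movements. Computes centre-of-mass velocity-position feasibility maps
    (forward-fall boundary, backward-fall boundary, zero-ankle-torque
    trajectory) for a simple inverted pendulum and for an inertia-variable
    (telescopic) inverted pendulum whose rotational radius is a cubic function
    of the centre-of-mass angle. Includes segment-based centre-of-mass
    estimation from reflective-marker trajectories, first-order propagation of
    mass-distribution uncertainty, admissible ankle-torque ranges under
    friction, foot-geometry and physiological torque constraints, seat-off
    state and trial classification with sensitivity/specificity reporting,
    between-model map similarity, an energy-strategy analysis against the
    zero-torque trajectory, and a synthetic motion-capture generator with an
    exhaustive-control labelling oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
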