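Package: respsim
Title: Lumped-Parameter Respiratory Mechanics of the Extremely Preterm Infant
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear lumped-parameter simulator of tidal breathing in the
    extremely preterm (~1 kg) infant. Couples Rohrer and Poiseuille airway
    resistances, a collapsible airway segment, a softplus chest-wall
    pressure-volume curve, a saturated-exponential lung distension curve
    multiplied by a sigmoidal alveolar recruitment fraction, and a
    Kelvin-Voigt viscoelastic tissue element into a four-state stiff ODE
    system driven by sinusoidal respiratory muscle pressure. Implements a
    breath-to-breath progressive volume-loss mechanism in which the
    recruitment curve drifts rightward in proportion to the compensatory
    over-distension of open alveoli, plus simulated interventions:
    laryngeal braking (raised expiratory upper-airway resistance), CPAP
    (stepped airway-opening pressure), variable breathing frequency, and
    apnea. Provides equilibrium parameterization (functional residual
    capacity, initial conditions, muscle-amplitude calibration), local
    stability analysis via Jacobian eigenvalues, a scenario registry,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
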