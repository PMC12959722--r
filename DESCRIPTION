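Package: stemshake
Title: Dynamics of Berry Fruit-Stem Systems Under Vibratory Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the detachment of soft berries (Blue Honeysuckle,
    Lonicera caerulea L.) during vibratory harvesting. The fruit-bearing
    branch is treated as a uniform-strength cantilever beam with a
    power-series steady-state solution of its forced bending vibration; the
    fruit plus stem is a base-excited torsional pendulum whose steady state
    is solved by harmonic balance for three stem orientations relative to
    the excitation direction (perpendicular, parallel, small-angle).
    Provides the parametric-instability boundary in the frequency-damping
    plane, axial-force and bending-moment envelopes with stress-based
    detachment criteria, an independent ODE/Floquet oracle for
    cross-validation, and a seeded synthetic-orchard simulator that
    reproduces harvest-efficiency and damage-ratio trends across excitation
    frequency, amplitude and stem-orientation cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    tidyr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
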