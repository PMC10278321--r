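Package: csfmanometry
Title: First-Order Hydraulic Modelling of Spinal Needle and Manometer
    CSF Pressure Measurement
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models the spinal needle-spinal manometer assembly used to
    measure cerebrospinal fluid (CSF) pressure at lumbar puncture as a
    first-order hydraulic system.  Provides Poiseuille and drop-weight
    estimators of needle resistance to flow, the characteristic time
    constant tau = R*A/rho, the closed-form exponential rise of the
    manometer column, extrapolation of the equilibrium CSF pressure from
    early readings, the low-pass frequency response of the assembly, a
    seeded ODE simulator with pulsatile forcing and a graduation-reading
    protocol, and nonlinear least-squares fitting of observed rise curves.
    Bench measurements for three 22G spinal needles and published
    resistance/time-constant pairs are bundled as plain-text fixtures
    together with an end-to-end reproduction report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), minpack.lm, deSolve, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
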