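Package: phagetrade
Title: Generalist and Specialist Phage Dynamics on Interacting Bacterial Prey
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phenomenological Lotka-Volterra-type model of two interacting
    bacterial prey species (resource competition or obligate cross-feeding
    mutualism) attacked by a generalist and a specialist lytic phage.
    Provides stiff ODE integration to steady state with extinction clamping,
    numerical fixed-point enumeration and Jacobian stability analysis, the
    analytic S* (R*-theory) invasion criterion for the two phage, bisection
    location of cost-of-generalism thresholds, scenario batteries and
    one- and two-dimensional parameter sweeps, Morris elementary-effects and
    Sobol variance-based global sensitivity analysis, and a synthetic
    plate-reader/plaque-assay observable generator with limit-of-detection
    censoring.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
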