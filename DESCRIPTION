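Package: sacburst
Title: Biophysical Model of Spontaneous Bursting in Developing Starburst
    Amacrine Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a conductance-based model of
    the spontaneous bursting of immature starburst amacrine cells (SACs), the
    autonomous bursters that drive stage II cholinergic retinal waves. The
    model couples a fast Morris-Lecar-type voltage/potassium pair to
    intracellular calcium and a slow calcium-gated potassium (sAHP) cascade.
    The package integrates the full five-variable stochastic system
    (Euler-Maruyama, compiled inner loop), analyses the fast subsystem with
    numerical bifurcation tools (fixed-point classification, saddle-node,
    Hopf and homoclinic detection, two-parameter region maps), detects
    calcium-defined bursts, fits the square-root law linking interburst
    intervals to the external current, and scripts in-silico pharmacology
    experiments (current pulses with calcium-channel blockade, developmental
    potassium-conductance scenarios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
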