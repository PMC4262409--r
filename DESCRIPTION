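Package: sfdtd
Title: High-Order Symplectic FDTD Simulation and SAR Dosimetry in Tissue Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An explicit high-order symplectic finite-difference time-domain
    (SFDTD) solver for Maxwell's equations in lossy dispersive biological
    tissue, with fourth-order staggered Yee stencils in space and a
    symmetric split-operator (Yoshida) composition in time. Includes a
    parametric concentric mother/fetus phantom with a built-in tissue
    dielectric table at 64 and 128 MHz, a Drude-plasma protective layer,
    total-field/scattered-field plane-wave injection, Mur and PEC
    boundaries, specific-absorption-rate (SAR) dosimetry with axis
    profiles, a second-order Yee baseline for comparison, and end-to-end
    experiments: a one-dimensional PEC-cavity long-term stability
    benchmark against a method-of-images analytic solution, and a
    two-dimensional shielding-angle study.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
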