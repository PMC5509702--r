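Package: cavijet
Title: Shock-Induced Cavitation Bubble Collapse and Polymer Damage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale particle simulation and analysis of shock-induced
    cavitation bubble collapse near a breakable bead-spring polymer, a
    coarse-grained stand-in for hyaluronan in the brain's perineuronal net.
    Provides a momentum-mirror shock tube with a carved bubble void and a
    velocity-Verlet NVE engine (cell-list Lennard-Jones fluid, harmonic
    bonds that rupture irreversibly), binned continuum fields (density,
    local velocity), water-hammer jet characterisation, shock-front speed
    measurement, and polymer damage reports. Includes the analytic
    water-hammer kinetic-energy scaling law (energy per frontal area
    D^3/(D+2d)^2 * p_p in N/m), the nine-case reference grid over bubble
    diameters 5/8/10 nm and post-shock pressures 2.65/7.97/16.2 GPa, the
    40 N/m rupture threshold classification, and the Young-Laplace bubble
    pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
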