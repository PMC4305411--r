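Package: colonysim
Title: Multi-Scale Simulation of Cell Colonies with Compartmentalized
    E-Cadherin Adhesion Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Center-based (off-lattice, individual-based) simulation of
    two-dimensional cell colonies in which every cell carries a
    compartmentalized E-cadherin/beta-catenin adhesion pathway. Per-cell
    ordinary differential equations move adhesion complexes between the
    cytosol and dynamically created cell-cell contact compartments; bound
    complex levels are translated into separation forces calibrated
    against dual-pipette measurements (210 nN anchor); cell mechanics
    combine Hertz contact repulsion with overdamped Stokes motion; and a
    stochastic cell cycle with pressure-triggered arrest (contact
    inhibition at 13 000 pN) drives colony growth. Three model variants
    are provided: static adhesion (Model 1), dynamic adhesion with
    inter-site redistribution (Model 2) and a separation-force framework
    (Model 3). Includes dual-pipette calibration by multi-start
    Nelder-Mead, colony metrics (neighbour histograms, mean contact
    force, exponential growth fits), scenario builders and CSV/JSON/YAML
    input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
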