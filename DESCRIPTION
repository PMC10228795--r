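Package: woundfield
Title: Reaction-Diffusion Modelling of JNK/AP-1 and JAK/STAT Bistability in Wounded Epithelia
Version: 0.1.0
Authors@R: person("Wound", "Field Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Simulates a four-species reaction-diffusion model of
    JNK/AP-1 and JAK/STAT signalling around a localized wound in a 1D
    epithelial field, with unidirectional- and mutual-repression network
    topologies. Provides log-uniform ensemble sampling of the
    dimensionless parameter space, steady-state detection by stiff
    implicit integration with an independent Newton root-finding oracle,
    classification of bistable spatial patterns by descriptive
    ("simple") and correlation-based ("observed") criteria,
    gradient-geometry summaries (half-maximum widths, curve
    intersections), parameter-density analyses, and utilities to
    aggregate, scale and LOESS-smooth fluorescence reporter line
    profiles. A synthetic-data module generates noisy reporter tracks,
    parametric reference profiles, and analytically labelled classifier
    fixtures so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
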