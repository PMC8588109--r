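Package: dendritrace
Title: Trajectory Analysis for Charged Peptide Dendrimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular configurations and trajectories of
    charged dendrimers and their host-guest complexes. Computes global shape
    descriptors (radius of gyration, asphericity from the gyration tensor,
    Kirkwood hydrodynamic radius, terminal-group radius), radial mass and
    charge profiles, cumulative charge and the effective charge/radius of the
    counterion double layer, the spherically symmetric Poisson potential with
    zeta potential and the soft-sphere cell-model prediction, geometric
    hydrogen-bond detection with continuous-lifetime statistics, planar-group
    (imidazole/guanidine) pairing maps over centre distance and inter-plane
    angle with pairing autocorrelation times, and a local contact criterion
    for guest-peptide complexation. Ships deterministic synthetic-configuration
    generators with known ground truth so every estimator can be validated
    without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
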