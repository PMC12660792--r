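Package: gnrhkit
Title: Docking-Pose Triage and Activation Analysis for Peptide-GPCR
    Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying peptide-bound class A G-protein-coupled
    receptor (GPCR) systems such as the gonadotrophin-releasing hormone
    receptor (GnRH1R).  Implements a staged elimination and candidate-selection
    protocol for protein-peptide docking decoys (cluster population, score and
    interface-energy gates, Mann-Whitney U statistics with Bonferroni
    correction and rank-biserial effect sizes, and Cbeta-Cbeta contact
    filters), together with a molecular-dynamics trajectory analysis suite:
    the TM3-TM6 activation metric with sustained-shift detection, hydrogen
    bond and salt-bridge statistics with lifetime analysis, water-mediated
    hydrogen-bond bridge networks with occupancy, radial distribution
    functions for hydration structure, backbone RMSD, an activation-signature
    panel, and sub-domain principal component analysis with kernel density
    population maps.  Planted-truth synthetic generators for decoy sets and
    helical-bundle trajectories make every stage testable without external
    data.  Results are returned as tibbles with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
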