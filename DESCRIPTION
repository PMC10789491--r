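Package: cryptabm
Title: Multi-Scale Agent-Based Simulation of the Mouse Intestinal Crypt
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An off-lattice, multi-scale agent-based model of the mouse
    small-intestinal crypt.  Each proliferative cell carries a cyclin/CDK
    cell-cycle protein network whose speed responds to intercellular
    pressure (contact inhibition of proliferation); cells interact through
    surface-tethered Wnt signals with a ZNRF3/RNF43-like niche feedback,
    Notch lateral inhibition, and an enterocyte-coupled BMP gradient.
    The model simulates crypt homeostasis, stem-cell ablation and recovery
    by dedifferentiation, CDK1-inhibition phenotypes (giant cells, mitotic
    death), and 5-fluorouracil pharmacokinetics with DNA/RNA damage,
    checkpoint apoptosis, and epithelial injury and regeneration.  Includes
    virtual BrdU pulse-chase and Ki-67 staining observers, scenario runners,
    and deterministic miniature fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
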