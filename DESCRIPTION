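Package: crinet
Title: System Mapping and Multilayer Epistatic Networks for Coupled Growth Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping pleiotropic control of two coupled growth traits
    (stem height and diameter in a full-sib tree population). A coupled
    regulatory interaction (CRI) system of Lotka-Volterra type splits each
    trait's growth rate into a self-regulated logistic part and an
    interaction-driven part; the system is embedded in a bivariate
    longitudinal likelihood with a first-order structured antedependence
    (SAD(1)) covariance to scan markers for genotype-specific growth
    dynamics. Genome-wide per-marker genetic-effect curves are clustered into
    modules with an EM-fitted Gaussian mixture whose mean curves are Legendre
    orthogonal polynomial expansions, and directional signed epistatic
    networks are reconstructed at module, submodule and marker level by
    LASSO regulator selection and ODE decomposition of each node's effect
    curve into independent and dependent components. Includes a simulator for
    full-sib genotypes and CRI-driven phenotypes at controlled heritability,
    and a power / false-positive-rate / ROC study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    glmnet,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
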