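Package: plasmidsim
Title: Stochastic Simulation of Plasmid Segregation in Dividing Yeast Nuclei
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Particle-based stochastic simulation of plasmid inheritance
    during Saccharomyces cerevisiae anaphase. The nucleus is modelled as two
    prolate spheroids joined by a cylindrical bridge whose dimensions change
    through time; a plasmid is a Brownian particle of finite radius confined
    to the moving domain by closest-point remapping. Includes estimators for
    plasmid diffusion coefficients from tracked jump sizes, mitotic stability
    and per-generation plasmid loss rates from colony counts, binomial
    confidence intervals for transmission traces, and a synthetic geometry
    generator so the full pipeline can be exercised without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
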