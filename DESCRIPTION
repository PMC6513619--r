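Package: heterospread
Title: Eden Growth, Selection and Lineage Dynamics of Range Expansions in
    Heterogeneous Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A generalized Eden lattice model of microbial range expansions
    in environments with quenched disorder, together with the analysis stack
    needed to study its population genetics and interface physics. Disorder
    sites at density rho reduce the local growth rate by a transparency
    factor k (impassable obstacles at k = 0), mutants carry a relative
    growth rate 1 + s, and wild-type divisions mutate with probability mu.
    The package simulates radial colonies and linear fronts with full
    division logging, extracts fronts and interface widths, estimates
    roughness and growth exponents (Family-Vicsek scaling), locates the
    pinning/percolation threshold, measures clone-size distributions, clone
    anisotropy, lineage fluctuations and pair-coalescence statistics, fits
    the selection-efficacy parametrization fMT(s) = f0*exp(ks*s), computes
    the DFE-weighted rate of adaptation, and infers mutation rates from
    replicate plating counts by simulation-based maximum likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
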