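Package: mipsim
Title: Atomistic Monte Carlo Simulation of Molecularly Imprinted Polymers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds united-atom models of molecularly imprinted polymers
    (MIPs) templated with pyrazine or pyrimidine in a methacrylic acid /
    ethylene glycol dimethacrylate mixture. Provides NPT Monte Carlo
    equilibration of the pre-polymerization liquid, quenching into a frozen
    porous matrix with template removal, energy-biased grand canonical Monte
    Carlo rebinding with Ewald and damped shifted-force electrostatics,
    simulated annealing of template complexes, and analysis tools for
    binding-site classification, energy histograms, pair distribution
    functions and selectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
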