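Package: propgen
Title: Evolutionary Dynamics Under Probabilistic Genotype-Phenotype Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying evolutionary dynamics when genotypes map
    probabilistically to phenotypes. Provides an agent-based serial-dilution
    simulator with overlapping generations, phenotypic noise at birth,
    spontaneous mutation and stochastic phenotype switching; a deterministic
    infinite-population integrator of the corresponding replicator-mutator
    dynamics; exact equilibria and coexistence phase diagrams for the
    two-genotype/two-phenotype model; the fitness-valley bridge equilibration
    time constant with analytical, Jacobian and trajectory-fit estimators; and
    a closed-form solution for bacterial persister resuscitation dynamics with
    a time-varying switching rate.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
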