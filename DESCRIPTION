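Package: nox1design
Title: Design Analysis of Nox1 Assembly and Disassembly Kinetics in
    Vascular Smooth Muscle Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mass-action kinetic modelling of NADPH oxidase 1 (Nox1)
    complex assembly, disassembly and subunit recycling in vascular
    smooth muscle cells. Provides the 8-state/16-flux reaction network,
    steady-state flux-balance parameterization from an 8-flux basis,
    seeded Monte-Carlo ensembles over initial subunit distributions and
    log-uniform fluxes, functional-effectiveness screens against
    responsiveness criteria and semi-quantitative AngII/PMA
    observations, and a comparison of the seven possible
    subunit-recycling module designs by steady-state fold change and
    on/off response times.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
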