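Package: actocap
Title: Capping-Protein-Regulated Branched Actin Network Growth at Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deterministic and stochastic simulation of Arp2/3-complex-mediated
    dendritic actin network growth at a membrane under finite, depleting protein
    pools. Implements the membrane-localized branching/capping reaction network
    (VCA-mediated Arp2/3 activation, seeding, autocatalytic branching, barbed-end
    elongation and capping), infinite-reservoir steady states and growth-phase
    detection, an effective-2D radial reaction-diffusion model of single-domain
    spreading, a Brownian-ratchet mapping from barbed-end density profiles to
    membrane-deformation morphologies (protrusion, concave, flat), a bulk
    pyrene-like polymerization emulator with tangent-method lag extraction, and a
    synthetic vesicle-ensemble generator with morphology summaries.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
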