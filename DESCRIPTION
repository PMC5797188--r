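Package: larvreg
Title: Standard-Brain Template Construction and Deformable Registration for
    Larval Drosophila CNS Image Stacks
Version: 0.1.0
Authors@R:
    person("larvreg", "developers", email = "larvreg@example.org",
           role = c("aut", "cre"))
Description: Builds a population-based standard brain template from 3D
    confocal stacks of the larval Drosophila central nervous system and
    registers subject scans onto it through a staged linear plus B-spline
    deformable pipeline.  Registration quality is scored automatically with
    two local confidence indicators (regional mutual information at the
    ventral nerve cord terminal, and normalized Eulerian strain combined
    with regional mutual information at the thoracic nerves); flagged scans
    can be corrected with landmark-guided multi-metric registration.
    Accuracy is evaluated with landmark registration error statistics
    against an expert gold standard.  A seeded phantom generator produces
    synthetic CNS-like multi-channel stacks with ground-truth transforms,
    landmarks and controlled failure modes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
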