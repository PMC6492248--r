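Package: cmsrefine
Title: Protein-Protein Complex Refinement in Contact Map Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for local refinement of docked protein-protein complexes
    using a contact-map-space (CMS) collective variable. Builds an interface
    contact map from an ensemble of docked solutions, evaluates the scalar CMS
    coordinate through a rational switching function, runs well-tempered
    metadynamics on that coordinate through a desk-scale Langevin surrogate
    sampler (with export of PLUMED inputs for production molecular dynamics),
    reconstructs the free energy surface, scores trajectory snapshots with a
    mixed function combining an interface energy score and the free energy
    surface, quantifies snapshot ranking error, builds ensemble-averaged
    refined models, and assesses model quality with CAPRI-style metrics
    (FNAT, LRMSD, IRMSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
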