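Package: slnopt
Title: Mixture-Process Designed Experiments for Solid Lipid Nanoparticle
    Formulation
Version: 0.1.0
Authors@R:
    person("slnopt", "maintainers", email = "slnopt@example.org",
           role = c("aut", "cre"))
Description: Tools for crossed mixture-process designed experiments as used in
    solid lipid nanoparticle (SLN) formulation development: simplex-centroid
    mixture designs crossed with factorial process grids, D-optimal subset
    selection by a Fedorov-style exchange algorithm, ordinary least squares
    fitting of multiplicative Scheffe-by-quadratic response models with ANOVA
    validation, Derringer-Suich desirability optimization over the simplex and
    process box, and isoresponse grid evaluation on ternary and process-plane
    slices. Ships a 66-run SLN study (particle size, polydispersity index,
    absolute zeta potential) and a seeded response simulator so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
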