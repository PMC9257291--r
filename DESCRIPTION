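Package: wingcontrast
Title: Ventral Wing Contrast Scoring and Phylogenetic Mixed-Model Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the colour contrast of bird ventral wings from images
    (RMS contrast of masked grey values) and from multi-scorer binary
    classification panels, assembles species-level ecological trait tables,
    and fits Bayesian phylogenetic Gaussian mixed models by parameter-expanded
    Gibbs sampling, with model averaging across a set of candidate phylogenies.
    Includes a synthetic-data generator (Yule trees, traits evolved under
    Brownian motion, patchwork wing images, scorer panels) with known ground
    truth so every stage of the pipeline can be verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    ape,
    png,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
RoxygenNote: 7.3.3
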