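Package: foragespec
Title: Individual Foraging Specialisation from Bio-Logging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies individual foraging specialisation in central-place
    foraging seabirds from GPS tracks, time-depth records, stable isotopes and
    regurgitate diets. Provides speed filtering and trip segmentation of GPS
    deployments, dive detection from 1-Hz depth series, a grid-cell space-use
    consistency index, circular statistics of trip headings, nested
    variance-components estimation of behavioural repeatability, Ward
    hierarchical clustering of individual foraging strategies, diet composition
    tables, and a seeded simulator of a central-place-foraging population with
    known ground truth for validating every estimator end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    nlme,
    ape,
    optparse
Config/testthat/edition: 3
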