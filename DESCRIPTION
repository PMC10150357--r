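Package: spheroidevo
Title: Cellular Potts Simulation of Tumor Evolution in Phenotype Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional cellular Potts model (CPM) of an avascular
    spheroid tumor growing inside healthy tissue, with nutrient-dependent
    cell division and death, differential cell-cell adhesion, random
    motility, and incremental phenotype mutation at division over a
    discrete 12x12 adhesion-by-motility grid.  The package provides the
    Metropolis lattice engine (compiled), a configurable simulation driver
    with period sweeps over an orbiting nutrient sink, and an analysis
    layer for phenotype-space centroid trajectories, mean squared
    displacement, evolution speed, distribution spread, radial event
    histograms, and replicate-sweep statistics, plus synthetic fixture
    generators with known ground truth for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
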