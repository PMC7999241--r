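Package: oliveOC
Title: Cluster-Based Estimation of Oil Content in Single Olives from Color and NIR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the oil content (percent of dry matter) of individual
    olives from tray images and near-infrared reflectance spectra. Olives are
    described by three illumination-invariant c1c2c3 color ratios plus eleven
    reflectance points in the 1710-1735 nm lipid absorption band, grouped by
    similarity with a minimum-group-size constrained k-means++ clustering so
    that each group is large enough for a gravimetric (Soxhlet) reference
    measurement, whose value is propagated to every member olive as its
    training label. A support vector regression tuned by simulated annealing
    then predicts oil content of single olives, evaluated with RMSECV under
    within-season, cross-season and mixed train/test schemes. Includes a
    seeded synthetic-orchard generator (tray images, triplicate spectra,
    ground truth) emulating the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    e1071,
    signal,
    data.table,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
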