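Package: benthoscape
Title: Spatially Balanced Survey Design and Design-Based Habitat Estimation
    for Shelf Seascapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing spatially balanced acoustic
    surveys of continental-shelf seabed habitat. Implements Generalized Random
    Tessellation Stratified (GRTS) sampling with master samples, reverse
    hierarchical ordering and prefix subsetting; nearest-neighbour plus 2-opt
    route planning for nested site subsets; substrate classification from
    bathymetry, slope and multibeam backscatter by explicit decision rules and
    by an angular-response-curve (ARC) probability-of-hardness method;
    design-based Horvitz-Thompson/Hajek estimation of substrate percentages
    and sessile-biota extent with local neighborhood variance confidence
    intervals; error-matrix accuracy statistics with Cohen's kappa; and a
    synthetic seascape simulator with known ground truth for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
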