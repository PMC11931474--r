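Package: synaptica
Title: Single-Synapse Colocalization and Spatial Interaction Analysis for
    Punctate Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies receptor localization at single synapses in
    multi-channel punctate immunofluorescence images. Detects fluorescent
    puncta with prominence-based maxima detection and marker-seeded
    watershed segmentation, defines synapses as overlapping pre- and
    postsynaptic puncta, gates them by vesicular transporter (VGLUT1/2)
    input type, classifies receptor puncta as post- or presynaptic, and
    measures spatial association between channels by fitting a Hernquist
    pairwise interaction potential to nearest-neighbor distance
    distributions with a Monte Carlo randomization test. Includes a
    ground-truthed synthetic image generator (Gaussian-PSF puncta fields
    and Gibbs point patterns) so every stage of the pipeline can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
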