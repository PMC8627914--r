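Package: airwaymorph
Title: Airway-Tree Morphometry from Binary Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the completeness of airway segmentations from chest CT.
    Extracts centerlines from 3-D binary masks by topology-preserving thinning,
    decomposes them into branches with bronchial generation numbers (trachea =
    generation 0, main bronchi = generation 1), measures branch length along the
    centerline and lumen diameter from the Euclidean distance transform sampled
    every millimeter, aggregates per-segmentation summaries (airway count, total
    airway length, median luminal diameter, per-generation tables), and compares
    paired segmentation variants with the exact Wilcoxon signed-rank test under
    Bonferroni correction. Includes a synthetic airway-phantom generator with
    known branch topology, radii and lengths, plus controlled degradations
    (distal pruning, lumen dilation, focal occlusion) so the whole pipeline is
    testable without patient data. Masks are read and written as NIfTI volumes
    or minimal DICOM slice series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
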