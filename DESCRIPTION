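Package: phaquant
Title: Single-Cell Quantification of Polyhydroxyalkanoate Granules from
    Fluorescence Micrographs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies intracellular polyhydroxyalkanoate (PHA) storage
    granules in single bacterial cells from multi-channel epifluorescence
    micrographs (DNA, membrane, and PHA stains). Implements Bernsen
    adaptive local thresholding with a circular window, 8-connected
    particle analysis with size and border filters, granule-to-cell
    assignment, and the conversion of per-cell PHA cross-sectional area
    fractions to volume fractions (sphere assumption) and mass fractions
    (density-ratio mixture model). Includes a synthetic micrograph
    generator with per-cell geometric ground truth for end-to-end
    validation, and growth-cycle metrics for methanotrophic enrichment
    cultures: headspace gas accounting, substrate consumption fractions,
    carbon- and nitrogen-based cell yields, and abundance-normalized PHA
    content.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
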