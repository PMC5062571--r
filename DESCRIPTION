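Package: wormhts
Title: High-Throughput On-Chip Screening of C. elegans Protein-Aggregation Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated high-throughput phenotyping of C. elegans
    polyglutamine (polyQ) aggregation on multi-well microfluidic imaging chips.
    Provides the chip data model with acquisition planning and stage-calibration
    geometry (rotation, tilt, substrate bending), a hydraulic equivalent-circuit
    solver with exit-channel width equalization, a ground-truth-bearing synthetic
    renderer of fluorescence z-stacks of worms immobilized in parallel channels,
    the aggregate-scoring image-analysis pipeline (focus selection by
    Laplacian-of-Gaussian variance, worm length measurement, vehicle-calibrated
    puncta segmentation), and plate-level screening statistics (Z'-factor,
    normalization, candidate and confirmed hit calling).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
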