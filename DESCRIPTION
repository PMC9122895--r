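Package: wormcensus
Title: Overlap-Aware Detection and Counting of C. elegans in Pond Assay Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for counting Caenorhabditis elegans in crowded 5-mm assay
    ponds where overlapping worms defeat one-class object detectors.
    Implements microscope-image background correction (morphological closing,
    difference-of-Gaussians pond-edge emphasis, circle Hough pond detection,
    pixelwise division), a synthetic overlapping-worm scene generator with
    ground truth in one-class (OCC) and multi-class (MCC) conventions,
    detection post-processing (IoU, per-class non-maximum suppression,
    confidence filtering, complete-IoU loss, the YOLO head filter-size rule),
    and the multi-class division-based counting and evaluation scheme
    (precision, recall, F1, average precision, detection-error statistics)
    that quantifies and corrects the overlapped-worm undercounting problem.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'boxes.R'
    'annotations.R'
    'detector.R'
    'evaluation.R'
    'wormgen.R'
    'experiment.R'
    'preprocess.R'
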