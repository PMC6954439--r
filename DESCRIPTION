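Package: mitoshape
Title: Quantification of Mitochondrial Network Morphology in Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments mitochondria in calibrated fluorescence microscopy images
    and classifies each segmented object as filament, rod, punctum or swollen
    from six shape features (area, aspect ratio, circularity, solidity, minimum
    Feret diameter and skeleton extension, the longest shortest-path between
    skeleton endpoints). Provides the full analysis chain -- maximum-intensity
    Z-projection, per-cell masking, rolling-ball background subtraction,
    Laplacian-of-Gaussian enhancement with contrast-limited adaptive histogram
    equalization, Yen thresholding, morphometry, rule-based classification and
    per-cell / per-group morphology statistics -- together with a synthetic
    scene generator that plants objects of known class and geometry for
    validation, and a command-line interface for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    optparse,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
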