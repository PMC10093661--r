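Package: budscan
Title: Tumor-Bud Density Mapping, Hotspot Selection and Scoring for Cytokeratin IHC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for automated tumor-budding quantification on
    cytokeratin (pan-CK) immunohistochemistry slides. Builds whole-slide
    tumor-bud density maps by disk-scan counting, extracts non-overlapping
    circular hotspots by greedy suppression, converts hotspot counts to the
    ITBCC three-tier budding score, and computes Shannon-entropy spatial
    heterogeneity biomarkers. Includes H-DAB color deconvolution with
    DAB-positive masking, construction of certainty-weighted pseudo-label
    training sets from teacher detections, detector evaluation metrics
    (sensitivity against sparse references, paired count comparison, hotspot
    agreement), and a seeded synthetic-slide generator with a planted densest
    hotspot for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
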