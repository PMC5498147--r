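Package: tiptrace
Title: Closed-Loop Tracking of Growing Root Tips and Migrating Cell Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-correlation based live tracking for time-lapse microscopy
    of autonomously moving specimens such as growing Arabidopsis root tips and
    migrating cell clusters. Implements median-of-three robust shift
    estimation on maximum intensity projections, cumulative-displacement
    position prediction for motorized stages, a per-step stage-movement
    safety limit, recomputation of specimen positions after rotation of the
    sample chamber about a calibrated centre, and growth-kinetics analysis
    (rates, day/night annotation, tip angle, side-intensity ratios).
    Includes a simulated microscope rendering synthetic growing roots with
    dividing cell files and generic moving cell clusters, so the whole
    closed loop is testable without hardware, plus multi-position TIFF
    time-point I/O and per-position hyperstack splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tiff,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
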