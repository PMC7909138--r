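Package: gazerep
Title: Representative Scanpaths from Groups of Eye-Tracking Fixation Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies a single representative scanpath -- spatial shape plus
    gaze duration -- for a group of observers viewing one stimulus. The
    pipeline removes outlier scanpaths with a boxplot rule on pairwise
    dynamic time warping (DTW) dissimilarity, extracts areas of interest
    (AOIs) by density-peaks clustering of pooled fixations with a
    weighted-geometric-mean exemplar threshold, locates AOI centers by a
    random-walk weighting scheme, aggregates the individual scanpaths into a
    constraint-valid AOI sequence minimizing average DTW (exhaustive
    heuristic search, candidate-constrained DTW barycenter averaging, or
    inter-observer-consistency selection), and attaches per-visit gaze
    durations averaged over matching AOI occurrences. A seeded synthetic
    scanpath generator with known AOI layout and consensus order makes every
    stage testable without eye-tracker data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
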