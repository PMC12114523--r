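Package: caliberkit
Title: Axon Caliber Morphometry and Dynamics from Membrane-Labeled Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies axon caliber from membrane-labeled fluorescence
    microscopy by perpendicular line scans: the caliber at a location is the
    distance between the two plasma-membrane intensity peaks. Provides
    arc-length centerline geometry, branch-point symmetry and tapering
    metrics, short-timescale caliber dynamicity (SD and percent relative SD),
    dividing-skin-cell analyses (region grouping, border-to-border length,
    round/flat frame selection, circular-arc path model), and the associated
    resampling statistics (paired sign-flip permutation test, exact
    Mann-Whitney U, BCa bootstrap confidence intervals). Includes a
    ground-truth phantom generator that renders pearled membrane-labeled
    axons and time-lapse caliber dynamics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
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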