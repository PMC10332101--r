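Package: vnoca
Title: En Face Vomeronasal Calcium Imaging, Behavioral Preference, and
    Activity-Mapping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for en face calcium imaging of vomeronasal
    sensory neuron dendritic knobs: F/F0 normalization, baseline-noise
    thresholded response detection with a repeatability criterion across
    repeated stimulus applications, stimulus-selectivity classification of
    responders (Venn partition of two-stimulus panels), knob density and
    total-knob estimation for density-normalized responder summaries, a
    behavioral preference statistic (log2 investigation-time ratio) with its
    one-sample test, activity-count quantification (percent positive of
    DAPI, cells per square micrometer, percent reduction), and a
    normality-gated two-group testing policy. A synthetic-data generator
    emulates every input kind (knob fields, fluorescence time series with
    planted responder classes, image stacks, investigation-bout logs, and
    region count tables) with known ground truth, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
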