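Package: bcsfusion
Title: Multi-Camera Depth-Image Body Condition Scoring with Fused
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automated dairy-cow body condition scoring (BCS) from
    multi-view time-of-flight depth cameras. Provides a synthetic
    depth-scene generator (parametric cow back surface with
    condition-dependent bone prominence, three camera views, floor and
    crush-bar background), pre-processing of raw millimetre depth frames
    into depth/binary/first-derivative channel stacks, phase sub-sampling
    augmentation with leakage-free cow-level train/test splitting, compact
    convolutional classifiers combined by early, mid or late (ensemble)
    fusion with cost-sensitive training, and tolerance-band evaluation
    reporting per-class and class-weighted precision, recall and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
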