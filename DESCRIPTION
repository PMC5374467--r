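Package: ecogdecode
Title: Sparse Linear Decoding of Trajectory and Muscle Activity from ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Band-resolved feature extraction, lag-embedded sparse Bayesian
    linear regression (automatic relevance determination), and leave-one-
    trial-out evaluation for decoding object trajectory and upper-arm muscle
    activity from multichannel electrocorticography (ECoG). Includes a
    synthetic-session generator that emulates an object-carrying task with
    extrinsic (trajectory-coding) and intrinsic (muscle-coding) cortical
    channels, electrode weight-map and per-channel contribution analyses,
    and mass-specific decoder transfer matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
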