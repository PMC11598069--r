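Package: accsym
Title: Motion Symmetry Analysis of Paired Accelerometer Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing left/right motion symmetry in rehabilitation
    exercises from paired smartphone accelerometer recordings. Recordings are
    segmented per repetition, each segment is described by time-domain (mean,
    standard deviation) and frequency-domain (relative spectral band power)
    features, and a percentage symmetry index per segment pair is averaged
    into a global symmetry criterion. Left- and right-side segments are also
    classified with a support vector machine, a Gaussian naive Bayes model,
    and a two-layer neural network under leave-one-out cross-validation. A
    synthetic-data generator produces paired recordings with controllable
    amplitude and frequency asymmetry so the full pipeline can be validated
    without access to study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
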