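Package: stridfd
Title: Fractal-Dimension Detection of Scarab Larval Stridulations in Soil Audio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects and semi-quantitatively estimates stridulations of
    soil-dwelling scarab beetle larvae (Melolontha spp.) in continuous
    mono WAV recordings. Audio is bandpass filtered, sliced into 2-second
    sections and short frames, and the geometric roughness of each frame
    is summarised by a madogram fractal-dimension estimate. Robust
    median/median-deviation standardisation within each section yields a
    summed fractal-distance series whose strongly negative excursions mark
    stridulation pulses; a vertical threshold, run-length filter and
    inter-peak-interval clustering turn these into events and a per-file
    stridulation-activity score (STRAC). A seeded synthetic soil-audio
    generator with ground-truth annotations makes the whole pipeline
    testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
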