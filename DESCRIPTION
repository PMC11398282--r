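Package: perclos
Title: Multi-Index Driver Drowsiness Detection from Facial Landmark Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects driver drowsiness from streams of 68-point facial
    landmarks using five visual indicators: eye aspect ratio (EAR), mouth
    aspect ratio (MAR), PERCLOS (percentage of eyelid closure per minute),
    gaze score, and head-pose Euler angles recovered by perspective-n-point.
    Thresholds for eye and mouth aperture are personalised per subject by a
    short initialisation routine. A temporal evaluator raises five
    non-exclusive alarms (asleep, yawning, head-distracted, gaze-distracted,
    drowsy) from sustained threshold crossings. Includes a synthetic
    landmark-stream generator with a closed-form alarm oracle, a pluggable
    video front-end contract, frame logging, session reports, and a
    command-line runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
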