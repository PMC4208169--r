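Package: harf
Title: Hierarchical Activity Recognition from Smartphone Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Training and recognition tools for smartphone-based human
    activity recognition from multimodal sensor logs (3-axis accelerometer,
    3-axis gyroscope, proximity sensor and GPS). Implements a bounded-memory
    adaptive Gaussian naive Bayes classifier that accumulates per-chunk
    running means and variances and combines them into class-conditional
    Gaussian activity models, together with a hierarchical, location-first
    recognition framework: registered-venue geofence matching, indoor/outdoor
    discrimination from GPS fix quality, candidate-set restriction for
    location-qualified physical activities, and a GPS speed heuristic that
    relabels fast outdoor movement as riding a car. Includes a seeded
    multimodal sensor simulator with known ground truth, sliding-window
    feature extraction, confusion-matrix evaluation utilities, and a
    command-line pipeline covering simulate, train, recognize and evaluate
    steps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
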