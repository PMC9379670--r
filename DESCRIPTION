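Package: usvloc
Title: Localization and Individual Assignment of Mouse Ultrasonic
    Vocalizations with a Compact Phased Microphone Array
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation, sound-source localization and per-mouse assignment
    of ultrasonic vocalizations (USVs) recorded with a compact square
    four-microphone phased array mounted next to a camera above a home cage.
    Includes a multitaper spectrogram front end with cepstral flattening, a
    watershed-based separation of temporally crossing syllables, a
    delay-and-sum (Bartlett) beamformer evaluated over camera-floor
    coordinates, a statistically calibrated assignment of each vocal segment
    to an individual mouse via a simulation-built confidence lookup table,
    audible broadband vocalization (squeak) rejection, microphone-position
    calibration, audible rendering of ultrasonic calls, and an acoustic array
    simulator that generates multi-channel recordings, snout tracks and
    ground truth for validating every stage without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
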