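Package: sixmwt
Title: Calibration-Free Six-Minute Walk Test Analysis from Smartphone Inertial Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses six-minute walk test (6MWT) trials recorded with a
    smartphone-grade inertial sensor worn at the mid lower back. From
    tri-axial linear acceleration and azimuth sampled at a jittery ~50 Hz,
    the pipeline corrects azimuth wrap-around, detects turns at the walkway
    ends, self-calibrates an adaptive locking period from the first seconds
    of walking, detects steps by shape similarity to previous steps, recovers
    missed steps, declares stops, times foot strikes from the raw forward
    acceleration, labels steps left/right with a tangent method on the
    mediolateral signal, and converts walkway traversals into total distance
    walked plus clinical gait outcomes (cadence, step and stride time,
    symmetry). A synthetic gait-signal generator with exact ground-truth
    annotations makes every stage testable without device recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
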