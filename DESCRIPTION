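Package: ohdtools
Title: Analysis Pipeline for Automated Olfactory Habituation/Dishabituation Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for olfactometer-based olfactory habituation/dishabituation
    (OHD) testing in rodents: builds the stimulus presentation schedule and the
    corresponding solenoid-valve event log, validates valve exclusivity, reads
    and summarizes total-VOC telemetry and centroid tracking traces, scores
    investigation bouts from a zone-and-direction rule on the tracked centroid,
    estimates habituation and dishabituation effects with bootstrap confidence
    intervals and sign-flip permutation tests, and generates fully synthetic
    sessions (valve log, VOC telemetry, trajectory, ground-truth bouts) for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
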