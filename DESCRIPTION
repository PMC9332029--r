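Package: scqmon
Title: Bed-Exit Behavior Recognition from Detection Traces via Status
    Classification Queueing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-frame bounding-box detection streams from a
    bed-facing camera into bed-related behavior events (on bed, off bed,
    return, nobody) using a per-frame movement-status rule and a
    multi-queue buffer (Status Classification Queueing): each frame's
    status is routed to a behavior-specific queue and a behavior is
    declared when its queue fills, after which all queues are flushed.
    Includes readers and writers for JSONL/CSV detection traces and
    ground-truth behavior segments, a seeded simulator of narrow
    field-of-view traces with detection dropout and flicker, clip-based
    recognition-rate evaluation, and precision/recall/F1 confusion
    metrics. No camera or object detector is required; the package
    operates purely on detection traces.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
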