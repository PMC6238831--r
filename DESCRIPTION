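Package: ulcermetrics
Title: Wound-Size Measurement and Healing Tracking from Plantar Foot
    Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale computational core of a diabetic-foot-ulcer
    self-monitoring workflow: detects a 1-cm green fiducial sticker to
    convert pixels to centimetres, segments the foot silhouette from a
    dark flash-lit background by Otsu thresholding, segments the ulcer
    with a scribble-seeded marker watershed (deterministic priority
    flood), turns segmentations into dated wound measurements (cm2 and
    ulcer/foot area ratio), assesses healing against the 4-week
    greater-than-50-percent area-reduction surrogate marker, schedules
    photo reminders, and emits capture-guidance tokens from frame
    streams.  A synthetic-fixture generator renders foot scenes,
    healing time series and capture sweeps with exact ground-truth
    masks so the whole pipeline is testable without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
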