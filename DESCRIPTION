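Package: swiftmigr
Title: Swift Migration Analysis from Light-Level Geolocation with Wind
    Support Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse long-distance bird migration recorded by
    light-level geolocators (GLS): threshold-method geolocation (longitude
    from solar-noon timing, latitude from day length) with equinox
    flagging, stopover segmentation of daily-position tracks, great-circle
    route metrics (distance, detour, migration and travel speed, percent
    flight, barrier-crossing durations), altitude-resolved tailwind and
    crosswind annotation from gridded pressure-level wind fields, and a
    departure-date counterfactual quantifying the wind support gained by
    departing on the actual date rather than up to three days earlier or
    later.  A synthetic-data generator produces scripted multi-bird
    migrations, geolocator-like light series and observation noise, and
    structured wind fields with analytically known properties, so every
    pipeline stage can be validated against a ground truth.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ncdf4
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
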