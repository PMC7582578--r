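Package: heatwatch
Title: Occupational Heat-Stress Monitoring from Weather and Wearable Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline analytics for an IoT occupational heat-stress monitoring
    platform. Implements group-level thermal-comfort assessment from weather
    data (wet-bulb temperature, thermal comfort index, environment- and
    time-of-day-specific correction weights, five-stage classification with
    responsive actions), wearable biosignal processing (zero-phase band-pass
    filtering and peak-based heart-rate estimation from photoplethysmography,
    Hampel outlier removal for skin temperature, core-temperature estimation
    from the skin-ambient gradient), and a Mamdani fuzzy-inference risk engine
    (pi-type input memberships, Karvonen-anchored heart-rate sets, centroid
    defuzzification, four risk categories with alerting). Includes a streaming
    per-worker monitoring pipeline, seeded synthetic generators for device and
    weather streams with ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
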