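Package: sleepagree
Title: Free-Living Validation of Consumer Sleep Wearables Against Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for validating consumer wearable sleep
    trackers (a smart ring and a smartwatch) against wrist actigraphy under
    free-living conditions. Scores 60-second actigraphy epochs as sleep or
    wake with the Cole-Kripke algorithm, detects nonwear with the Troiano
    wear-time rule, extracts and cleans nightly sleep periods, ingests
    per-night ring summaries and event-level watch streams (with a
    PPG/movement/step validation cascade), computes nonstaging sleep
    parameters (total sleep time, wake after sleep onset, sleep efficiency,
    sleep onset latency) per night and device, and quantifies device
    agreement with paired t tests, Bland-Altman bias and limits of agreement,
    satisfactory-range coverage, Pearson correlation, and gender subgroup
    tests. A synthetic multi-device study generator with controllable
    ground-truth sleep architecture and device biases makes every stage
    testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
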