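Package: sleepwin
Title: Diary-Free Detection of the Sleep Period Time Window from Wrist
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects the sleep period time (SPT) window from raw wrist-worn
    tri-axial accelerometer recordings without a sleep diary. Implements the
    heuristic z-angle distribution-of-change algorithm (HDCZA): a rolling
    5-minute median of absolute changes in estimated arm angle, a per-day
    adaptive threshold (10th percentile times 15), detection of sustained
    below-threshold blocks, gap absorption, and selection of the longest
    block per noon-noon day. Also provides the naive L5+/-6 reference
    algorithm based on the ENMO acceleration metric, sleep-episode scoring
    within the detected window (sustained inactivity bouts, sleep efficiency,
    wake after sleep onset), comparison machinery against sleep diaries and
    polysomnography hypnograms (signed differences, mean absolute error,
    epoch-level accuracy and c-statistic, simulated-wakefulness padding for
    in-bed-only recordings, stage sensitivities), a parameter sensitivity
    sweep, and a seeded synthetic-data generator producing raw recordings,
    hypnograms, and diaries with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
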