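Package: hrvsd
Title: Symbolic Dynamics and Stationarity-Aware Heart Rate Variability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of short-term heart rate variability (HRV) under acute
    psychological stress. Implements binary symbolic dynamics of RR-interval
    differences (0V/1V/2V pattern categories under a sign and a 35 ms threshold
    encoding), two nonstationarity diagnostics (recursive heuristic segmentation
    and the restricted weak stationarity test), classical time- and
    frequency-domain HRV parameters (SDNN, RMSSD, variance-adjusted LF/HF band
    powers from a 4 Hz resampled, detrended, Hanning-windowed, zero-padded FFT),
    and a nonparametric cohort statistics layer (Friedman, Skillings-Mack for
    missing data, Holm-adjusted pairwise post-hocs, Mann-Whitney contrasts).
    Includes a synthetic Trier-Social-Stress-Test cohort generator so the whole
    pipeline can be exercised end to end without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    car,
    graphics,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
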