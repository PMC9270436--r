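Package: chronolfp
Title: Diurnal Analysis of Chronic LFP Band-Power Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chronically sensed local field potential
    (LFP) band-power streams of the kind logged by implanted deep brain
    stimulation devices (one averaged power value per 10 minutes, in
    microvolt-peak units). Implements iterative z-score outlier
    interpolation, daily median detrending, 30-minute-binned time-of-day
    fits, the fraction of variance explained by time of day, a day-shift
    temporal shuffling permutation test, Welch periodogram periodicity
    estimation, sleep-diary epoch masking and event alignment, day/night
    value distributions, raw-LFP band-power estimation with a
    movement-epoch power table, exact small-sample paired tests, and a
    synthetic-data generator that emulates chronic sensing streams with
    known ground truth so that every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
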