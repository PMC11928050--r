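Package: cricketsong
Title: Detection and Analysis of Cricket Calling Songs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated analysis of field-cricket calling songs from PCM
    WAV recordings. Syllables are detected on the normalized amplitude
    envelope with a double (hysteresis) threshold and zero-amplitude boundary
    refinement, grouped into chirps by gap duration, and summarized into the
    standard song parameters: chirp and syllable durations, inter-chirp and
    inter-syllable intervals, syllable-count proportions, and dominant
    frequency. Includes the statistical battery used to compare treatment
    groups of recordings (Welch t-test, F-test of variances, normality check
    with a transform ladder, nested t-test on individual means, chi-square
    goodness of fit on call-type proportions) and a seeded synthetic
    stridulation generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
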