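Package: fpvstag
Title: Frequency-Tagging Analysis of Fast Periodic Visual Stimulation EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies periodic oddball responses in fast periodic visual
    stimulation (FPVS) EEG experiments. Provides a seeded synthetic-study
    generator (frequency-tagged EEG with 1/f background noise and face-like
    image sets), the standard preprocessing chain (zero-phase Butterworth
    band-pass, line-noise notches, anti-aliased resampling, sequence
    segmentation, average re-referencing), frequency-domain quantification
    of oddball and base responses (integer-cycle cropping, single-sided
    amplitude spectra, neighbor-bin signal-to-noise ratios, baseline
    subtraction and z-scores, harmonic selection, summed-harmonic responses
    over regions of interest), time-domain analysis (low-pass filtering,
    base-frequency notch removal, five-cycle epoch averaging, cluster-based
    permutation tests), stimulus image-set statistics (luminance, contrast,
    head-orientation ratio, face-area fraction, radial amplitude spectra
    with log-log slope fits, two-set permutation tests), and an
    orchestrator that runs a complete study analysis from a configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
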