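Package: pupilbands
Title: Discovery of Pupillography Frequency-Band Limits via HRV Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for locating the low- and high-frequency band
    limits of the pupil-diameter signal whose spectral power features best
    track canonical heart-rate-variability (HRV) features. Implements HRV and
    pupillography preprocessing (boxplot outlier removal, shape-preserving
    cubic gap filling, iterative singular spectrum analysis artifact repair,
    zero-phase filtering), Burg autoregressive spectral estimation on sliding
    windows, an exhaustive non-overlapping band sweep on a 0.01 Hz grid,
    per-run Pearson/Spearman correlation of band-power features, Fisher-Z
    group aggregation with cluster-based permutation correction, and
    geometric-mean ranking of band combinations. A synthetic generator of
    coupled RR-interval and pupil-diameter recordings with planted spectral
    structure makes every stage testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
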