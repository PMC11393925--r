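Package: channelpat
Title: Channel-Rank EEG Features, Ensemble k-NN and Symbolic Lobe Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feature engineering and interpretable classification for
    multi-channel EEG segments. Per-timepoint descending ranking of channel
    amplitudes turns a segment into a sequence of channel indices; overlapping
    index pairs are histogrammed into C^2 transition features (ChannelPat);
    iterative neighborhood component analysis (INCA) selects an
    accuracy-maximizing feature prefix; an ensemble k-nearest-neighbor
    classifier (tkNN) pools 60 hyperparameter configurations and 58
    iterative-majority-voting outcomes and keeps the most accurate of the 118;
    selected features decode into a four-letter brain-lobe alphabet (F, T, P,
    O) whose sentences are summarized by symbol histograms, transition
    matrices and Shannon entropies. Includes CSV and EDF segment readers, a
    synthetic dataset generator for end-to-end validation, and
    confusion-matrix performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    class,
    optparse
Config/testthat/edition: 3
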