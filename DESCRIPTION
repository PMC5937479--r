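Package: anuracall
Title: Temporally-Aware Classification of Anuran Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level featurization of anuran (frog and toad) recordings
    with 18 MPEG-7-style low-level audio descriptors, Jensen-Shannon
    divergence feature ranking, and a family of temporally-aware classifiers:
    local interquartile-range (LIQR) feature construction, sliding-window
    (SW) and recurrent sliding-window (RSW) frame stacking, discrete-
    observation left-right hidden Markov models over a Linde-Buzo-Gray
    vector-quantization codebook, and vector-autoregressive (VAR) segment
    models with weighted-AIC order selection.  Includes confusion-matrix
    metrics with single-point AUC, bootstrap confidence intervals and
    pairwise outperformance probabilities, and a seeded synthetic call
    generator (pulsatile croaks vs tonal whistles over noise) so the full
    pipeline is testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    MASS,
    class,
    rpart,
    nnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
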