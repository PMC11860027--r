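Package: painsense
Title: Multimodal Pain Sentiment Analysis from Face Images and Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying pain intensity from paired face images and
    vocal audio clips. Provides declarative convolutional network architecture
    specifications with exact analytic shape propagation and parameter
    accounting, a small neural-network trainer (convolutional and dense) with
    progressive multi-resolution and transfer/fine-tuning training schemes, a
    handcrafted audio feature bank (FFT statistics, MFCCs, spectral
    centroid/bandwidth/contrast), score-level fusion rules (sum, product,
    weighted sum) and decision-level majority voting, evaluation protocols
    (stratified splits, classification metrics, one-tailed two-sample t-test),
    and a seeded synthetic generator of paired labelled image and audio samples
    for end-to-end testing without any licensed clinical dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    class,
    e1071,
    nnet,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
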