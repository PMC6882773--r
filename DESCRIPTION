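Package: b2s
Title: Brain-to-Speech Unit-Selection Decoding from Electrocorticographic
    High-Gamma Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs audible speech directly from multichannel
    electrocorticographic (ECoG) recordings of speech motor cortex by
    concatenative unit selection: logarithmic high-gamma (70-170 Hz) power
    features are extracted at a 10 ms frame rate, and for every test frame
    the 150 ms Hanning-windowed speech unit whose training feature vector
    maximizes cosine similarity is retrieved and overlap-added into a
    waveform.  Includes the full evaluation stack (log-mel spectrogram
    Pearson correlations per word, randomized-selection chance level with
    empirical significance tiers, short-time objective intelligibility and
    its logistic mapping to transcription accuracy), grouped 5-fold
    cross-validation with disjoint word sets, per-region channel subsets,
    causal and centered feature contexts, and a synthetic paired
    neural/audio session generator with a tunable neural-acoustic coupling
    for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
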