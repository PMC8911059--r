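Package: spectroinflame
Title: FTIR Hyperspectral Chemometrics for Intestinal Inflammation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Fourier-transform infra-red (FTIR) microspectroscopy of
    bowel tissue: synthetic generation of labelled hyperspectral colitis cohorts,
    spectral preprocessing (cropping, rubber-band baseline correction,
    Savitzky-Golay second derivatives, standard normal variate normalisation,
    background removal, representative averaging), band-integration biochemistry
    quantification with Welch tests, partial least squares discriminant analysis
    (PLS-DA) with venetian-blind cross-validation and variable importance in
    projection (VIP) scores, multi-class colitis-severity classification with a
    stacked ensemble of neural-network, support-vector, random-forest and
    k-nearest-neighbour learners, and a neural-network hyperspectral layer
    segmenter, orchestrated end to end from a single seeded configuration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    nnet,
    randomForest,
    e1071,
    caret,
    jsonlite,
    yaml,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
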