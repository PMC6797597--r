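Package: snn6ma
Title: Shallow Convolutional Networks for DNA N6-Methyladenine Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether the central adenine of a fixed-length (41 bp)
    DNA window is an N6-methyladenine (6mA) site using a lightweight
    one-dimensional convolutional network (convolution with ELU activation,
    group normalization, max pooling, dropout, a fully connected layer, and a
    sigmoid output), trained with stochastic gradient descent with momentum,
    binary cross-entropy loss, L2 regularization, early stopping on
    validation accuracy, best-checkpoint restoration, and
    reduce-learning-rate-on-plateau. Provides two sequence encodings
    (one-hot, and chemical-property triads combined with cumulative
    nucleotide frequency), a k-fold cross-validation protocol with a held-out
    validation fold, five evaluation metrics (accuracy, sensitivity,
    specificity, Matthews correlation coefficient, area under the ROC
    curve), cross-species evaluation of a frozen model, a planted-motif
    synthetic benchmark generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
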