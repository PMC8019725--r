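Package: startletrace
Title: Fluorescence-Trace Quantification and Startle-Habituation Analysis for
    Mauthner-Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing in vivo glutamate and calcium line-scan
    recordings from the zebrafish Mauthner-cell startle circuit together with
    the behavioural trial tables collected alongside them. Provides dF/F0
    computation, Gaussian smoothing, Z-plane and X-Y motion correction by
    cross-correlation, threshold-based transient detection, biexponential
    kinetic fitting with quality control, stimulus-locked peak extraction,
    intensity-response and short-term depression curves, release-threshold
    estimation, exponential habituation fits, and the behavioural statistics
    (latency classification, Kolmogorov-Smirnov, binomial laterality, t-tests
    and one-way ANOVA) used in startle-habituation studies. A synthetic-data
    generator with known ground truth emulates the imaging and behavioural
    data so every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
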