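Package: corrclust
Title: Clustering Coefficients Tailored to Correlation Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Triangle statistics for correlation-based networks such as
    functional connectivity matrices. Implements local and global clustering
    coefficients built on the three-way partial correlation coefficient and on
    Gaussian partial mutual information, which discount the pseudo-correlation
    expected from indirect paths through a focal node, alongside the
    conventional unweighted (thresholded) and weighted (Barrat, Onnela,
    Zhang-Horvath) clustering coefficients for comparison. Includes the
    Hirschberger-Qu-Steuer random covariance null model, white-noise null
    correlation matrices, structured synthetic time-series generators,
    connectivity summaries, delimited-text input/output and a batch runner
    with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
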