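Package: paradiverge
Title: Expression and Sequence Divergence of Paralogous Gene Pairs Under Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of paralogous gene pairs under multiple stress
    conditions: classification of pairs by differential-expression pattern
    (both genes, exactly one, or neither differentially expressed per
    condition), stress-sharing expression clusters and enhancing/decreasing
    trajectories over time courses, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction, regression of rescaled within-pair expression
    correlation on synonymous divergence, randomized-pair permutation nulls
    for selection-pressure statistics, and a soft-thresholded co-expression
    network of differentially expressed paralogs and transcription factors.
    Includes a codon-sequence evolution simulator that generates paralog
    pairs, expression matrices and differential-expression tables with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    seqinr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
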