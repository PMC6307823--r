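Package: tetherTE
Title: Tethered-Function Reporter and Ribosome-Profiling Translational-Efficiency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of tethered-function mRNA reporter assays
    and matched ribosome-profiling/RNA-Seq experiments in yeast. Implements
    the repression-ratio calculus for Western/qPCR reporter data with explicit
    error propagation, first-order mRNA decay and half-life estimation from
    promoter-shutoff time courses, polysome gradient fraction distributions,
    a genome-wide translational-efficiency contrast stage with a
    negative-binomial Wald stand-in test and threshold-based gene-set
    selection, and gene-set statistics (hypergeometric overlaps, notched
    box-plot summaries, pentile and codon-optimality binning). A synthetic
    data generator with known ground truth emulates every experimental design
    so that each stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
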