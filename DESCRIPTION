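Package: DOMwave
Title: Seasonality and Functional Redundancy of Dissolved Organic Matter
    and Microbial Time Series
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing parallel time series of dissolved organic
    matter (DOM) molecules and prokaryoplankton from oligotrophic ocean
    time-series stations. Implements quality-control filtering of untargeted
    LC-MS feature tables (Gaussian peak-shape screening, data-adaptive blank
    subtraction, detection-frequency, retention-time consistency and pooled-QC
    relative standard deviation rules), construction of uniform monthly-grid
    series with replicate averaging and linear interpolation, Morlet
    continuous-wavelet seasonality classification with white-noise permutation
    significance and 12-month band reconstruction, cohort-level depth
    intersection and peak-season summaries with Kolmogorov-Smirnov comparison
    of median wavelet power, contribution-evenness functional redundancy from
    contig-level KEGG-ortholog tables with single-copy marker gene richness,
    and monoisotopic-mass annotation with ppm matching. A seeded synthetic
    data generator emulates the sampling design so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    ggplot2
Config/testthat/edition: 3
biocViews: Metabolomics, Metagenomics, Microbiome, TimeCourse, QualityControl
RoxygenNote: 7.3.3
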