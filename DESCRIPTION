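Package: biochemnet
Title: Biochemometric Ranking of Bioactive Constituents by NMR
    Heterocovariance and MS Molecular Networking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint MS- and NMR-based biochemometric analysis of
    microfractionated extracts. Per-fraction MS feature intensities
    (MZmine-style quantification tables with MGF fragment spectra) and
    binned 1H NMR spectra are correlated with bioactivity over short
    consecutive runs of fractions ("packages"). The MS branch builds a
    feature-based molecular network from modified-cosine fragment
    similarity and color-codes nodes by Pearson correlation with
    activity; the NMR branch computes a heterocovariance (HetCA)
    pseudospectrum whose upward red signals mark activity-correlated
    proton resonances. Both lines of evidence are combined into a ranked
    shortlist of putative bioactive constituents. A synthetic-data
    module simulates fraction series with known actives so the whole
    workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
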