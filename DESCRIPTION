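Package: asmipr
Title: Splice-Score Analysis for Molecular Inversion Probe Junction Assays
Version: 0.1.0
Authors@R: person("asmipr", "maintainers", email = "asmipr@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting tissue-specific alternative splicing from
    multiplexed exon-exon junction measurements produced by molecular
    inversion probe (asMIP) assays read out on tag microarrays, by
    high-throughput sequencing of probe tags, or by junction-spanning qPCR.
    Implements array background subtraction with unused-feature controls,
    dilution-series dynamic-range selection, log2 signal assembly,
    reference-based R-scores, model-based M-scores fitted by Tukey median
    polish, symmetric score cutoffs, ternary splice calls, and
    concordance-index evaluation against control labels. A synthetic-data
    generator emulates the additive probe-effect model of the assay on all
    three platforms so the entire pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    MASS,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
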