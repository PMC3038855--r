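Package: cnamcr
Title: Copy Number Aberration Calling and Minimal Critical Regions from Array CGH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-color oligonucleotide array-CGH profiles of
    acute myeloid leukemia cohorts. Calls aberrant segments from probe-level log2
    ratios with a circular-style recursive binary segmentation stand-in for the
    Agilent ADM2 step, maps linear ratios to copy states, separates germline copy
    number variants and immunoglobulin/T-cell-receptor VDJ deletions from acquired
    copy number abnormalities, derives minimal critical regions by cross-patient
    interval intersection, compares therapy-related and de novo cohorts, renders
    ISCN-like interval notation and revised karyotype strings, and simulates
    clonal-fraction-attenuated cohorts with ground truth for recovery testing.
    Ships transcriptions of the published per-patient CNA tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
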