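Package: peakscape
Title: H3.3 Occupancy Landscapes, Mutual-Exclusivity Statistics and
    Protective Drug-Screen Scoring for Neuroblastoma Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying histone-variant (H3.3) occupancy
    landscapes from CUT&RUN peak calls across genotype groups of
    neuroblastoma cell lines: dual-threshold reproducible-peak
    compilation, reference peak sets, size-filtered fragment counting, a
    moderated differential-occupancy test, and constitutive / enriched /
    depleted / overlapping (C/E/D/O) peak classification.  Reference
    peaks can be annotated with G-quadruplex and R-loop-forming-sequence
    overlap, promoter/enhancer location, ChromHMM-state concordance and
    state-13 expansion.  Companion modules provide cohort contingency
    statistics for mutation-by-clinical-factor association and
    mutual exclusivity (Fisher, chi-square, Cochran-Mantel-Haenszel,
    Clopper-Pearson intervals), protective AUC scoring of dose-response
    drug screens, small closed-form assay metrics, and a synthetic-data
    generator with planted ground truth so that every stage is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
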