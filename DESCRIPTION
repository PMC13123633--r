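Package: wolfscan
Title: Radiation Dosimetry, Lineage-Specific Selection Scans and
    Dose-Correlated Expression Screens for Wildlife Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studies of chronic radiation exposure in
    wild mammal populations. Reconstructs per-animal internal and external
    radiation dose rates from 137Cs and 90Sr measurements and computes
    lifetime doses; applies genotype quality filters and windowed LD pruning
    to multi-population genotype matrices; scans for lineage-specific
    selection with per-site Weir-Cockerham FST, Cavalli-Sforza branch
    lengths, the population branch statistic (PBS) and population branch
    excess (PBE) with empirical outlier calling and nearest-gene annotation;
    screens transcripts for dose-correlated expression with module eigengene
    trait tests and pathway principal components; estimates leukocyte
    proportions from bulk expression by non-negative least squares against
    reference profiles; and generates fully seeded synthetic datasets with
    known ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
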