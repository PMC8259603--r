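Package: sparsegs
Title: Sparse-Testing Genomic Selection with Multi-Environment GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating sparse-testing genomic selection
    in early-stage plant breeding trials. Simulates multi-environment testcross
    trials of bi-parental doubled-haploid families, builds genomic relationship
    matrices from dominant presence/absence markers, optimizes which individuals
    are phenotyped in which environment using per-individual CDmean reliabilities,
    selects historical training individuals by average genomic relationship, fits
    multi-environment GBLUP by REML with unstructured, factor-analytic, or
    diagonal genotype-by-environment covariance and heterogeneous residuals, and
    evaluates CV1/CV2 sparse-testing schemes by Pearson accuracy of genomic
    estimated breeding values against per-environment BLUEs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, lme4, stats, utils, graphics, grDevices, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
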