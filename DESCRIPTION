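Package: secretoscope
Title: Peptide-Level Label-Free Quantification and Secretome Comparison
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Quantitative analysis of cell secretomes measured by label-free
        LC-MS/MS at the peptide level. Implements condition-wise peptide
        occupancy filtering and the two-peptide rule, rescaled z-score
        normalization of log2 intensities, per-protein mixed linear models
        (random donor and peptide intercepts, fixed batch) for fold-change
        estimation against a baseline condition, preranked gene-set
        enrichment with a gene-label permutation null, multi-condition
        secretome set comparison, and companion immunoassay and viability
        statistics with normality-gated test selection. A synthetic-data
        generator with known ground truth (donor, batch, peptide and
        condition effects; intensity-dependent missingness) makes every
        stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, S4Vectors, SummarizedExperiment,
        lme4, lmerTest, nortest, jsonlite
Suggests: testthat (>= 3.0.0), fgsea, optparse
biocViews: Proteomics, MassSpectrometry, Normalization,
        DifferentialExpression, GeneSetEnrichment, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
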