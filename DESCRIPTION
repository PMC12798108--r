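Package: saltomics
Title: Salt-Tolerance Screening and Multi-Omics Integration for Germplasm Panels
Version: 0.1.0
Authors@R: person("Pepper", "Screening Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating salt tolerance in crop germplasm panels and
    integrating the downstream omics evidence. Implements the membership-function
    composite evaluation (D value) of relative growth traits, salt tolerance
    indices and injury indices, standard plant physiological formulas
    (relative electrolyte leakage, ethanol-extract chlorophyll equations,
    Na+/K+ ratios, time-course summaries), relative qPCR expression by the
    2^(-ddCt) method, threshold screening of differentially expressed genes and
    differentially accumulated metabolites with multi-set overlaps and
    hypergeometric enrichment under Benjamini-Hochberg false-discovery-rate
    control, and FDR-controlled Pearson metabolite-gene co-regulation networks
    with Gephi-compatible export. A synthetic-data module generates every
    pipeline input with known ground truth so the whole chain is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
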