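Package: metconnect
Title: Metabolic Connectivity Profiling of Drug-Treated Tumor Metabolomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed Spearman correlation networks over metabolite
    abundance profiles and a phenotype trait (tumor volume or cell number),
    controls the false discovery rate with Benjamini-Hochberg, extracts
    locally dense modules with a full reimplementation of the MCODE
    algorithm, summarizes pathways by their eigenmetabolite (first principal
    component of the member metabolites), contrasts networks and pathway
    connectivity between control and drug-treated conditions, and computes
    the tumor growth inhibition (TGI) metric for xenograft growth curves.
    Ships a synthetic metabolomics generator with planted correlation blocks
    for benchmarking the whole pipeline against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
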