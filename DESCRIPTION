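Package: soilvirome
Title: Viral Contig Triage, Host Linking, and Community Statistics for Soil Viromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision layer for soil virome studies: screening and tripartite
    filtering of candidate viral contigs with greedy identity clustering,
    lysogenic/lytic lifestyle classification from marker annotations, virus-host
    linking by CRISPR spacer, tRNA and genomic-homology evidence, auxiliary
    metabolic gene (AMG) retention and categorization, and the community and
    microcosm statistics (RPKM, Shannon diversity, Bray-Curtis, ANOSIM, Mantel,
    FDR-thresholded correlation networks, cumulative CO2 and the microbial
    metabolic quotient qCO2, ANOVA with Duncan letters). Includes a synthetic
    community generator with planted, machine-readable ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
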