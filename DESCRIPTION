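Package: novomp
Title: De Novo Metaproteomics Filtering, Database Assembly and Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-acquisition computation for de novo assisted metaproteomics:
    a six-tier confidence filter for de novo peptide-spectrum matches (score,
    charge, length, and normal-quantile cutoffs on precursor mass error,
    retention-time shift and collisional cross-section shift), lowest-common-
    ancestor guided resolution of BLAST homology candidates and assembly of a
    non-redundant protein sequence database, taxonomic annotation with the
    three-specific-peptide detection rule and peptide-intensity taxon and
    biomass quantification, COG and taxon-by-pathway functional rollups, SILAC
    labeling-efficiency and spike-in limit-of-detection analytics, and seeded
    synthetic-data generators with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
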