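Package: chemcov
Title: Chemical-Space Coverage Analysis of Substance Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Standardizes and deduplicates multi-source chemical collections
    (salt/solvent stripping, isotope clearing, neutralization, InChI identity),
    aggregates per-substance genotoxicity assay results into conservative hit
    calls for the six standard test types (Ames, in vitro MCGM, in vitro and
    in vivo MN and CA), and quantifies how well a query domain such as
    pesticide substances is covered by reference substance sets: exact InChI
    overlap, Tanimoto similarity overlap on radius-2 2048-bit circular
    fingerprints, Murcko scaffold diversity and gap ranking, SMARTS
    functional-group proportion differences, and complementary PCA and UMAP
    projections of the merged chemical space. Includes a synthetic-data
    generator with full ground-truth bookkeeping so that every pipeline stage
    is testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
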