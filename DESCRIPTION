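Package: phenologr
Title: Cross-Species Phenolog Discovery and eQTL Mapping Between Worm and Human
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers phenologs -- pairs of phenotypes in Caenorhabditis elegans
    and Homo sapiens whose associated gene sets share significantly more
    orthologous genes than expected by chance -- using an upper-tail
    hypergeometric overlap test computed in ortholog-group space. Builds
    ortholog-group backgrounds from pairwise ortholog calls, parses
    gene-phenotype and gene-disease association catalogs, performs single-marker
    LOD scans over expression trait matrices with QTL peak detection, flanking
    probe windows, genomic region queries and eQTL hotspot counting, and
    composes these into disease-to-QTL, region-to-disease, QTL-to-disease and
    phenotype-comparison workflows. Includes a seeded synthetic-data generator
    with planted phenologs and planted cis/trans eQTLs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
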