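Package: cgpdgroup
Title: Chemical Grouping and Clustering from CGPD Tetramers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates curated chemical-gene, chemical-phenotype,
    chemical-disease and gene-disease evidence (Comparative Toxicogenomics
    Database dump format) together with NCBI gene2go annotations into CGPD
    tetramers: evidence blocks linking a chemical to a gene it interacts
    with, a Gene Ontology phenotype linked to both, and a disease linked to
    both chemical and gene. Tetramers can be filtered by organism, by 28
    coarse tissue groups, and by disease evidence class; chemicals are then
    grouped by shared gene/phenotype/disease keys and the groups clustered
    by Lin semantic similarity of phenotypes over the GO DAG and by
    Tanimoto similarity of chemical membership lists. Clusters are scored
    by hypergeometric over-representation of regulatory chemical classes
    and of GO terms. A seeded fixture generator emulates all input formats
    at small scale with planted group structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    dplyr,
    tibble,
    tidyr,
    igraph,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
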