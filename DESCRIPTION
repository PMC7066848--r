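Package: platmine
Title: Sentence-Level Literature Mining of Platinum-Resistance Genes in
    Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for mining platinum-resistance genes
    from corpora of ovarian-cancer abstracts. Parses MEDLINE flat files,
    segments abstracts into sentences, recognises gene mentions with a
    deterministic dictionary matcher, and counts sentence-level
    co-occurrence of genes with platinum-drug and resistance terms.
    Downstream stages rank genes by count, test annotation-term
    over-representation with a Bonferroni-corrected hypergeometric test,
    build the protein-interaction subnetwork induced on frequently
    mined genes and rank nodes by degree, and cluster per-subtype
    normalised gene-by-subtype co-occurrence profiles with
    complete-linkage agglomeration under the Chebyshev metric. A
    synthetic corpus generator with planted signal makes every stage
    testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
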