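Package: gilnet
Title: Condition-Layered Gene Co-Expression Networks with Genetic Trait Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds collections of condition-specific gene co-expression
    networks (Gene Interaction Layers, GILs) from an expression compendium.
    Samples are pre-clustered with K-means so that correlations confined to a
    subset of conditions are not diluted away; each sample group yields one
    network thresholded by a random-matrix-theory (RMT) test on the
    nearest-neighbour spacing distribution of the thresholded correlation
    matrix's eigenvalues. Overlapping gene modules are discovered per network
    with the link-community method (edge clustering maximizing partition
    density), scored for functional term enrichment by Fisher's exact test,
    and related across networks by Cohen's kappa on enriched terms and the
    Jaccard index on gene content. QTL intervals and GWAS SNP windows are
    mapped onto module genes to score module-trait overlap and to nominate
    proximal biomarker SNPs. Includes deterministic synthetic-data generators
    that plant condition-specific modules and congruent trait intervals for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    igraph,
    limma,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    withr,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
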