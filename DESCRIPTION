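Package: lncflow
Title: Discovery, Classification and Network Integration of Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Maintainer", "lncflow", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for long noncoding RNA (lncRNA) discovery from
    assembled transcriptomes: a seven-step candidate filter (length, exon count,
    read coverage, FPKM, open reading frame size, protein evidence, scaffold-end
    margin), strand-aware positional classification into sense, antisense,
    intronic, bidirectional and intergenic classes, adjacent protein-coding gene
    (apcGene) linking within a distance window, antisense lncRNA-mRNA duplex
    scoring, miRNA hairpin precursor matching by local alignment, an exact
    conditional count test for differential expression between unreplicated
    pooled libraries with Benjamini-Hochberg correction, hypergeometric term
    enrichment, and assembly of a typed lncRNA-miRNA-mRNA competing endogenous
    RNA (ceRNA) network with miRNA hub scoring. Ships a synthetic-data generator
    that plants ground truth for every stage so the full pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
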