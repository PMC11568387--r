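Package: starrpop
Title: Enhancer Activity, Differential Regulation and Population Genomics
    from STARR-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for massively parallel reporter (STARR-seq) enhancer
    analysis across populations: windowed Poisson peak calling from paired
    DNA-input and plasmid-derived RNA fragment counts, cross-replicate
    consensus enhancer construction, per-replicate activity quantification
    (log2 RNA/DNA fold-change), social-versus-solitary differential activity
    via a sociality-by-library interaction model, feature-priority
    enhancer-to-gene assignment, permutation region-overlap and
    hypergeometric gene-set statistics, pooled allele-frequency association
    with enhancer activity, position weight matrix allele-effect calling
    with exact score-distribution p-values, Hudson Fst and the Population
    Branch Statistic with derived-allele polarization, and a synthetic-data
    generator emulating a six-population, three-replicate STARR-seq design
    so the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
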