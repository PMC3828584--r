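Package: quadrec
Title: Recessive Variant Prioritization in Quad Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Family-based prioritization of autosomal-recessive candidate
    variants from whole-exome data of a quad pedigree (two unaffected
    parents, two or more affected siblings). Implements consequence
    classification on transcript models (CDS/codon arithmetic, splice-region
    windows, HGVS c./p. and legacy IVS naming), exclusion against known-site
    databases, a recessive segregation scan for shared-homozygous and
    in-trans compound-heterozygous genes, protein domain mapping against the
    myosin XVa domain table, alignment-column conservation assessment, and a
    fully deterministic synthetic quad-exome simulator with a planted causal
    gene for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
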