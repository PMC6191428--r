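Package: somasig
Title: Somatic Variant Filtering, Mutational Signatures, and
    Driver-Signature Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tumor/normal somatic-genomics analysis toolkit: two-caller
    consensus filtering of SNVs with a panel of normals and COSMIC-based
    rescue, indel filtering with a pseudo panel of normals, germline
    deleteriousness classification, two-caller structural-variant consensus
    with breakpoint-window corroboration, gene-level copy-number calling
    with chromosomal-instability features, 96-context mutational-signature
    extraction by Kullback-Leibler non-negative matrix factorization with
    non-negative least-squares attribution, and the downstream
    nonparametric association framework relating driver-gene mutation
    status to signature activity, including the homologous-recombination
    deficiency versus APOBEC balance analysis. A built-in synthetic cohort
    generator with full truth bookkeeping makes every stage testable
    against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    pracma,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
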