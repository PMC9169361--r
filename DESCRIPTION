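Package: ApobecSig
Title: APOBEC Mutagenesis Enrichment Scoring and Mutational Signature
    Analysis for Somatic Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies APOBEC-driven mutagenesis in tumor cohorts from
    MAF-format somatic mutation calls. Computes the per-sample APOBEC
    mutagenesis enrichment score (AMES) from TCW-motif cytosine mutations
    against a local sequence background, stratifies samples into enrichment
    levels, builds 96-channel trinucleotide substitution matrices, extracts
    de novo mutational signatures by non-negative matrix factorization with
    cophenetic rank selection, annotates them against reference SBS
    catalogs by cosine similarity, and fits per-sample exposures by
    non-negative least squares. Also provides tumor mutational burden,
    DNA damage response pathway mutation status, pairwise mutation
    co-occurrence testing, and bulk-expression immune scores (ssGSEA,
    cytolytic activity, linear risk signatures), together with seeded
    synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
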