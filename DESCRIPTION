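Package: nmibcGenomics
Title: Genomic Subtyping and Mutation Timing for Non-Muscle-Invasive
    Bladder Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the genomic dissection of
    non-muscle-invasive bladder cancer (NMIBC) cohorts from somatic
    mutation tables and allele-specific copy-number segments: cancer cell
    fraction estimation with clonal/subclonal and early/late timing,
    whole-genome doubling and weighted genome instability index (wGII)
    calling, 96-channel mutational-signature deconvolution (EM fitting to
    a catalog and de novo KL-NMF extraction) with APOBEC tCw enrichment,
    trinucleotide-rate dN/dS selection with early/late timing odds
    ratios, GISTIC-like recurrent copy-number scoring, margin-preserving
    co-occurrence/mutual-exclusivity testing, Brunet-NMF consensus
    subtyping of binary genomic event matrices, expression-based subtype
    and marker-panel scoring, and cross-cohort Fisher/BH comparison. A
    synthetic-cohort generator with full ground truth makes every stage
    testable without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    survival,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
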