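Package: guidecraft
Title: CRISPR Guide Selection, Off-Target Scoring and Assay Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds CRISPR guide RNAs in an input sequence for SpCas9, SaCas9
    and Cpf1, enumerates genomic off-targets within a mismatch budget, scores
    them with MIT hit and CFD penalty models, aggregates a per-guide
    specificity score, predicts microhomology-mediated out-of-frame deletion
    propensity, and designs the downstream wet-lab reagents: cloning oligos,
    validation and off-target PCR primers with nearest-neighbor melting
    temperatures, amplicon-sequencing manifests, and barcoded oligo pools for
    saturating-mutagenesis screens. Includes a deterministic synthetic-genome
    fixture generator with planted off-target sites and a brute-force search
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
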