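Package: neoscan
Title: Proteogenomic Neoantigen Identification from Somatic Variants and
    Immunopeptidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a proteogenomic neoantigen
    identification workflow for tumour samples: consensus merging and hard
    filtering of multi-caller somatic variant calls, construction of a
    patient mutanome from missense variants, enumeration of
    mutation-spanning peptide windows at HLA class I (8-11mer) and class II
    (15mer) lengths, consensus (median) binding-affinity prediction with
    agretopicity, candidate scoring and per-allotype ranked tables, direct
    neoantigen detection by matching eluted immunopeptides against the
    mutanome, and SBS96 mutational-signature extraction (NMF), reference
    matching (cosine) and exposure refitting (NNLS). A synthetic-data
    module generates all inputs with known ground truth so every stage and
    the end-to-end pipeline are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    pracma,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
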