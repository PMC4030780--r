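Package: triotriage
Title: Trio Exome Variant Triage for Fetal Structural Abnormalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant triage for trio (proband-mother-father) exome studies of
    fetal structural abnormalities. Merges per-caller variant call sets,
    screens trios for de novo single-nucleotide variants and indels with
    monozygotic-twin-aware independence collapse and allele-balance-based
    mosaicism flagging, filters inherited variants under homozygous-recessive,
    compound-heterozygous and X-linked hemizygous models, filters copy-number
    variant calls by confidence, common-variant overlap, gene overlap and mode
    of inheritance, classifies candidate genes with an evidence-based decision
    tree into highly-likely / possibly / unknown causality categories, and
    computes cohort-level statistics (synonymous-depletion test, recurrent-gene
    probability, candidate-count summaries). Includes a synthetic family-cohort
    generator with a truth table so every stage is testable end to end, and a
    packaged fixture encoding a 30-proband prenatal cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
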