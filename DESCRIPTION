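Package: mttscreen
Title: Screening and Evaluation of Mitochondrial tRNA-Thr (MT-TT) Variants
    in Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for screening variants of the mitochondrial
    tRNA-Thr gene (MT-TT, rCRS m.15888-15953) in case-control cohorts such
    as Leber's hereditary optic neuropathy (LHON) studies. Calls variants
    against the revised Cambridge Reference Sequence (rCRS, NC_012920.1),
    maps them onto the tRNA cloverleaf (tRNAdb numbering), evaluates
    Watson-Crick base-pair disruption and the cross-species conservation
    index, classifies variants into known, putative and polymorphic
    categories by configurable rules, computes per-variant and aggregate
    carrier statistics including the Pearson chi-square case-control
    comparison, and assigns mtDNA haplogroups from full-genome variant
    profiles via a defining-variant tree. A synthetic-data generator
    produces cohort FASTA files, multi-species alignments and variant
    profiles with exactly specified carrier counts, so the whole analysis
    is reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
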