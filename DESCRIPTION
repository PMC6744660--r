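Package: musadicho
Title: Ploidy, Nucleotide Variation and Bunch-Phenotype Concordance in
    Inflorescence-Dichotomous Plantain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse inflorescence dichotomy in plantain (Musa spp.,
    AAB genome): crop-cycle concordance of bunch phenotypes across plant and
    ratoon crops, single-nucleotide-polymorphism detection from gapped
    nucleotide alignments with transition/transversion and
    synonymous/non-synonymous classification, ploidy determination from
    metaphase chromosome counts and from flow-cytometry DNA-content
    histograms against a triploid internal standard, and seeded
    synthetic-data generators (phenology tables, variant-implanted
    alignments, chromosome-count tables, fluorescence histograms) that carry
    ground-truth labels so every stage of the pipeline can be validated
    end-to-end without field, cytology or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
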