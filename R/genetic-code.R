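# Standard genetic code with three-letter amino-acid symbols, plus the
# purine/pyrimidine partition used for substitution classification.

# Stop codons are "Ter"; the reference generator never emits them in frame.
GENETIC_CODE_3 <- c(
  TTT = "Phe", TTC = "Phe", TTA = "Leu", TTG = "Leu",
  CTT = "Leu", CTC = "Leu", CTA = "Leu", CTG = "Leu",
  ATT = "Ile", ATC = "Ile", ATA = "Ile", ATG = "Met",
  GTT = "Val", GTC = "Val", GTA = "Val", GTG = "Val",
  TCT = "Ser", TCC = "Ser", TCA = "Ser", TCG = "Ser",
  CCT = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACT = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCT = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  TAT = "Tyr", TAC = "Tyr", TAA = "Ter", TAG = "Ter",
  CAT = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAT = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAT = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  TGT = "Cys", TGC = "Cys", TGA = "Ter", TGG = "Trp",
  CGT = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGT = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGT = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
)

STOP_CODONS <- names(GENETIC_CODE_3)[GENETIC_CODE_3 == "Ter"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_3), STOP_CODONS)

NUCLEOTIDES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# Translate one codon (character scalar, ACGT) to its 3-letter amino acid.
translate_codon <- function(codon) {
  aa <- unname(GENETIC_CODE_3[codon])
  if (is.na(aa)) {
    md_stop(sprintf("not a valid codon: '%s'", codon),
            "musadicho_invalid_argument")
  }
  aa
}

base_class <- function(base) {
  ifelse(base %in% PURINES, "Pu",
         ifelse(base %in% PYRIMIDINES, "Py", NA_character_))
}
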