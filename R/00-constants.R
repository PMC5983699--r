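# Shared alphabet and genetic-code constants (collated first).

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# Amino-acid translation table (bacterial/plastid code; identical to the
# standard code over the 64 codons, start-codon differences are irrelevant
# here).
GENETIC_CODE_PLASTID <- Biostrings::getGeneticCode("11")

ALL_CODONS <- sort(as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                   DNA_BASES, paste0)))

SENSE_CODONS <- names(GENETIC_CODE_PLASTID)[GENETIC_CODE_PLASTID != "*"]
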