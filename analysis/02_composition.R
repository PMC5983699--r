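#!/usr/bin/env Rscript
# Stage 2: per-genome composition statistics (the characteristics table) and
# codon usage, from the GenBank files written by stage 1.

suppressPackageStartupMessages(library(plastcomp))

gb_files <- Sys.glob(file.path("results", "synthetic", "*.gb"))
stopifnot(length(gb_files) > 0)
records <- lapply(gb_files, read_genbank)

summaries <- do.call(rbind, lapply(records, genome_summary))
write.table(summaries, file.path("results", "genome_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

code <- Biostrings::getGeneticCode("11")
cu <- codon_usage(extract_coding(records[[1]])$sequence)
cu_df <- data.frame(codon = names(cu$codon_counts),
                    amino_acid = unname(code[names(cu$codon_counts)]),
                    count = unname(cu$codon_counts))
cu_df$per_mille <- round(1000 * cu_df$count / cu$total_codons, 2)
write.table(cu_df, file.path("results", "codon_usage.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

aa <- sort(cu$aa_percent, decreasing = TRUE)
cat(sprintf("%s: %d bp, GC %.2f%%; %d codons; most frequent aa %s (%.2f%%)\n",
            summaries$id[1], summaries$length[1], summaries$gc_overall[1],
            cu$total_codons, names(aa)[1], aa[[1]]))
cat("wrote results/genome_summary.tsv and results/codon_usage.tsv\n")
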