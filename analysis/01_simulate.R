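#!/usr/bin/env Rscript
# Stage 1: generate the four-taxon synthetic plastome set used by every
# downstream stage, and write the genomes plus ground truth under
# results/synthetic/.

suppressPackageStartupMessages(library(plastcomp))

seed <- 2026
cfg <- sim_config(seed = seed)
root <- generate_root(cfg)
sim <- evolve_on_tree(root, cfg)

outdir <- file.path("results", "synthetic")
emit_synthetic(sim, cfg, outdir)

cat(sprintf("simulated %d taxa from a %d bp root genome (%d genes)\n",
            length(sim$records), nchar(root$record$sequence),
            length(root$record$features)))
cat(sprintf("planted: %d SSRs, %d dispersed repeats, %d gene losses, %d hotspot spacers\n",
            nrow(root$truth$planted_ssrs), nrow(root$truth$planted_repeats),
            nrow(cfg$gene_losses), length(root$truth$hotspot_regions)))
cat("wrote", outdir, "\n")
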