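#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Writes a cohort of 12 ASD / 18 AST specimens (VP tissue available for a
# subset, mirroring the study's final sample sizes), 2-5 three-channel fISH
# images per specimen per region, binding densities coupled to latent mRNA at
# the region-specific target correlations, and genotypes at the three OXTR
# SNPs with medium-to-high pairwise D'.

library(fishcoloc)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 7L
data_dir <- "results/data"

manifest <- write_fixture_set(cohort_spec(seed = seed), outdir = data_dir)

imgs <- do.call(rbind, lapply(manifest$images, as.data.frame))
cat("simulated", manifest$n_specimens, "specimens,",
    nrow(imgs), "images into", data_dir, "\n")
print(table(imgs$region))
cat("images per specimen, range:",
    paste(range(table(imgs$specimen_id, imgs$region)[
      table(imgs$specimen_id, imgs$region) > 0]), collapse = "-"), "\n")
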