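#!/usr/bin/env Rscript

# Generate the synthetic study inputs: caller VCFs with designed
# filter failures, a reference proteome with expression, a missense
# table, donor allotype PSSMs, an immunopeptidome with spiked
# neoantigens, and SBS96 catalogs. Every downstream script reads from
# results/simulated_inputs; ground truth lands in truth.json.

suppressPackageStartupMessages(library(neoscan))

seed <- 20260101
data_dir <- "results/simulated_inputs"

cfg <- generator_config(seed = seed)
sim <- generate_all(cfg, data_dir)

cat("wrote", length(list.files(data_dir, recursive = TRUE)),
    "files to", data_dir, "\n")
cat("variants:", sim$truth$variants$n_variants,
    "| passing filters:", sim$truth$variants$n_pass, "\n")
cat("spiked neoantigens:",
    paste(sim$truth$spike$sequence, collapse = ", "), "\n")
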