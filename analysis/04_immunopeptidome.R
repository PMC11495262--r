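#!/usr/bin/env Rscript

# Summarize the eluted immunopeptidome (FDR <= 0.01, per-class
# deduplication, length distributions, motif-based allotype
# assignment) and match peptides against the mutanome to call
# directly observed neoantigens.

suppressPackageStartupMessages(library(neoscan))

data_dir <- "results/simulated_inputs"
out_dir <- "results"

records <- read_peptide_table(file.path(data_dir, "peptides.tsv"))
dedup <- dedupe_peptides(records, fdr_max = 0.01)

hist1 <- length_distribution(dedup$pooled[["I"]])
hist2 <- length_distribution(dedup$pooled[["II"]])
utils::write.table(rbind(cbind(hla_class = "I", hist1),
                         cbind(hla_class = "II", hist2)),
                   file.path(out_dir, "length_distribution.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

pssms <- read_pssm_set(file.path(data_dir, "pssms"))
assignments <- assign_allotypes(dedup$pooled[["I"]], pssms)
utils::write.table(assignments,
                   file.path(out_dir, "allotype_assignments.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

proteome <- read_proteome(file.path(data_dir, "proteome.fasta"))
missense <- read_missense_table(file.path(data_dir, "missense.tsv"))
mutanome <- build_mutanome(proteome, missense)
observed <- match_mutanome(unlist(dedup$pooled, use.names = FALSE),
                           mutanome, proteome)
utils::write.table(observed,
                   file.path(out_dir, "observed_neoantigens.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(dedup$n_retained, "records at FDR <= 0.01;",
    length(dedup$pooled[["I"]]), "unique class I and",
    length(dedup$pooled[["II"]]), "unique class II peptides\n")
cat("observed neoantigens:\n")
print(observed[, c("sequence", "protein_id", "mutanome_id",
                   "residue_pos", "mut_pos_in_peptide",
                   "il_ambiguous")])
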