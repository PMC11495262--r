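#!/usr/bin/env Rscript

# Build the personal mutanome from the missense table, enumerate
# mutation-spanning windows (8-11-mers for class I, 15-mers for
# DRB1), predict consensus binding with three jittered PSSM
# predictors, score candidates and write per-allotype/length ranked
# tables.

suppressPackageStartupMessages(library(neoscan))

seed <- 20260101
data_dir <- "results/simulated_inputs"
out_dir <- "results"

proteome <- read_proteome(file.path(data_dir, "proteome.fasta"))
missense <- read_missense_table(file.path(data_dir, "missense.tsv"))
mutanome <- build_mutanome(proteome, missense)
windows <- mutanome_windows(mutanome, lengths = c(8:11, 15L))
write_proteome_fasta(mutanome, file.path(out_dir, "mutanome.fasta"))

pssms <- read_pssm_set(file.path(data_dir, "pssms"))
predictors <- lapply(1:3, function(i) {
  pssm_predictor(paste0("synthpred", i), pssms,
                 jitter_sd = if (i == 1) 0 else 0.15,
                 jitter_seed = derive_stream_seed(
                   seed, paste0("predictor", i)))
})

cfg <- generator_config(seed = seed)
candidates <- predict_candidates(windows, predictors,
                                 cfg$class1_allotypes,
                                 cfg$class2_allotypes)
binders <- filter_binders(candidates, max_nM = 500)
tables <- rank_tables(binders)
write_rank_tables(tables, file.path(out_dir, "ranked"), top_k = 10)

cat(nrow(mutanome), "mutanome entries,", nrow(windows), "windows,",
    nrow(candidates), "candidates,", nrow(binders),
    "binders < 500 nM,", length(tables), "ranked tables\n")
top <- tables[["HLA-A*03:01|9"]]
if (!is.null(top)) {
  print(utils::head(top[, c("rank", "gene", "mt_peptide", "mt_nM",
                            "wt_nM", "score")], 5))
}
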