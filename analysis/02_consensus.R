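#!/usr/bin/env Rscript

# Merge the three caller VCFs into a consensus somatic set, apply the
# hard filters (VAF > 0.05, depth > 20, alt reads > 5) and report the
# mutational burden.

suppressPackageStartupMessages(library(neoscan))

data_dir <- "results/simulated_inputs"
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

callers <- c("mutect2", "varscan", "strelka")
calls <- do.call(rbind, lapply(callers, function(cl) {
  read_caller_vcf(file.path(data_dir, paste0(cl, ".vcf.gz")), cl)
}))
consensus <- merge_caller_calls(calls, priority = callers)
filtered <- apply_hard_filters(consensus)

write_consensus(consensus, file.path(out_dir, "consensus.vcf.gz"),
                file.path(out_dir, "consensus_summary.tsv"))

cat(nrow(calls), "caller records ->", nrow(consensus),
    "consensus variants ->", nrow(filtered), "after hard filters\n")
cat("mutational burden:",
    round(mutational_burden(nrow(filtered)), 3), "mutations/Mb\n")
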