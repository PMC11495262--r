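# End-to-end orchestration: consensus -> mutanome -> prediction/scoring
# -> ranked tables; in parallel, immunopeptidome summarization and
# mutanome matching; optionally an SBS signature summary. A manifest
# records seed, thresholds, per-stage counts and output checksums so a
# re-run with an identical config is verifiably identical.

#' Pipeline run configuration
#'
#' @param vcfs Named character vector of caller VCF paths, names are the
#'   caller identifiers.
#' @param priority Caller priority order (default the VCF names).
#' @param proteome Reference proteome FASTA path.
#' @param missense Missense variant table path (TSV).
#' @param peptides Eluted-peptide table path (TSV).
#' @param pssm_dir Directory of PSSM files for the donor allotypes.
#' @param class1_allotypes,class2_allotypes Donor typing; class II is
#'   restricted to DRB1.
#' @param thresholds Hard-filter thresholds ([filter_thresholds()]).
#' @param max_nM Binding cutoff for candidate tables (default 500).
#' @param fdr_max Peptide FDR cutoff (default 0.01).
#' @param class1_lengths,class2_length Peptide lengths per class.
#' @param top_k Rows per table in the combined candidate summary.
#' @param n_predictors Synthetic PSSM predictors to register (>= 2 so
#'   the consensus median aggregates disagreeing algorithms).
#' @param predictor_jitter_sd Weight perturbation of predictors 2..n.
#' @param sbs_catalogs,sbs_reference Optional SBS catalog / reference
#'   signature matrix paths; the signature summary runs when both are
#'   given.
#' @param sbs_k Signatures to extract in the summary (default 4).
#' @param seed Seed for the seeded parts of the run (predictor jitter,
#'   NMF restarts).
#' @param out_dir Run output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(vcfs, priority = names(vcfs), proteome, missense,
                       peptides, pssm_dir,
                       class1_allotypes, class2_allotypes = character(),
                       thresholds = filter_thresholds(), max_nM = 500,
                       fdr_max = 0.01, class1_lengths = 8:11,
                       class2_length = 15L, top_k = 10,
                       n_predictors = 3, predictor_jitter_sd = 0.15,
                       sbs_catalogs = NULL, sbs_reference = NULL,
                       sbs_k = 4, seed = 1, out_dir = "neoscan_run") {
  cfg <- as.list(environment())
  files <- c(vcfs, proteome, missense, peptides)
  absent <- files[!file.exists(files)]
  if (length(absent) > 0L) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  if (!dir.exists(pssm_dir)) stop("pssm_dir not found: ", pssm_dir)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `vcfs` is a mapping of
#' caller name to path.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$vcfs <- unlist(y$vcfs)
  if (!is.null(y$thresholds)) {
    y$thresholds <- do.call(filter_thresholds, y$thresholds)
  }
  do.call(run_config, y)
}

stage_log <- function(log, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  c(log, msg)
}

#' Run the full workflow end-to-end
#'
#' Stages: (1) consensus merge and hard filtering of the caller VCFs;
#' (2) mutanome construction and window enumeration from the missense
#' table; (3) consensus affinity prediction, agretopicity, scoring,
#' binder filtering and per-allotype/length ranked tables; (4)
#' immunopeptidome deduplication, length distributions, allotype
#' assignment and mutanome matching; (5) optional SBS signature
#' extraction/matching/refitting. A failing stage halts only the stages
#' that depend on it; independent branches still run. All outputs plus
#' `manifest.json` land in `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  results <- list()
  failed <- character()

  run_stage <- function(stage, deps, fun) {
    blocked <- intersect(deps, failed)
    if (length(blocked) > 0L) {
      log <<- stage_log(log, stage, "skipped (failed upstream: ",
                        paste(blocked, collapse = ", "), ")")
      failed <<- c(failed, stage)
      return(NULL)
    }
    tryCatch(fun(), error = function(e) {
      log <<- stage_log(log, stage, "ERROR: ", conditionMessage(e))
      failed <<- c(failed, stage)
      NULL
    })
  }

  results$consensus <- run_stage("consensus", character(), function() {
    calls <- do.call(rbind, lapply(names(config$vcfs), function(cl) {
      read_caller_vcf(config$vcfs[[cl]], cl)
    }))
    consensus <- merge_caller_calls(calls, config$priority)
    filtered <- apply_hard_filters(consensus, config$thresholds)
    write_consensus(consensus, file.path(out, "consensus.vcf.gz"),
                    file.path(out, "consensus_summary.tsv"),
                    config$thresholds)
    log <<- stage_log(log, "consensus", nrow(calls), " calls -> ",
                      nrow(consensus), " consensus -> ", nrow(filtered),
                      " after hard filters")
    list(consensus = consensus, filtered = filtered)
  })

  results$mutanome <- run_stage("mutanome", character(), function() {
    proteome <- read_proteome(config$proteome)
    missense <- read_missense_table(config$missense)
    mutanome <- build_mutanome(proteome, missense)
    lengths <- sort(unique(c(config$class1_lengths,
                             config$class2_length)))
    windows <- mutanome_windows(mutanome, lengths = lengths)
    write_proteome_fasta(mutanome, file.path(out, "mutanome.fasta"))
    utils::write.table(windows, file.path(out, "windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log <<- stage_log(log, "mutanome", nrow(mutanome), " entries, ",
                      nrow(windows), " mutation-spanning windows")
    list(proteome = proteome, mutanome = mutanome, windows = windows)
  })

  results$ranking <- run_stage("ranking", "mutanome", function() {
    pssms <- read_pssm_set(config$pssm_dir)
    predictors <- lapply(seq_len(config$n_predictors), function(i) {
      pssm_predictor(paste0("synthpred", i), pssms,
                     jitter_sd = if (i == 1) 0 else
                       config$predictor_jitter_sd,
                     jitter_seed = derive_stream_seed(
                       config$seed, paste0("predictor", i)))
    })
    candidates <- predict_candidates(results$mutanome$windows, predictors,
                                     config$class1_allotypes,
                                     config$class2_allotypes,
                                     config$class1_lengths,
                                     config$class2_length)
    binders <- filter_binders(candidates, config$max_nM)
    tables <- rank_tables(binders)
    write_rank_tables(tables, file.path(out, "ranked"), config$top_k)
    log <<- stage_log(log, "ranking", nrow(candidates), " candidates -> ",
                      nrow(binders), " binders < ", config$max_nM,
                      " nM -> ", length(tables), " ranked tables")
    list(predictors = predictors, candidates = candidates,
         binders = binders, tables = tables)
  })

  results$immunopeptidome <- run_stage(
    "immunopeptidome", "mutanome", function() {
      records <- read_peptide_table(config$peptides)
      dedup <- dedupe_peptides(records, config$fdr_max)
      pssms <- read_pssm_set(config$pssm_dir)
      hist1 <- length_distribution(dedup$pooled[["I"]])
      hist2 <- length_distribution(dedup$pooled[["II"]])
      assignments <- assign_allotypes(dedup$pooled[["I"]], pssms)
      observed <- match_mutanome(
        unlist(dedup$pooled, use.names = FALSE),
        results$mutanome$mutanome, results$mutanome$proteome)
      utils::write.table(observed,
                         file.path(out, "observed_neoantigens.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(rbind(cbind(hla_class = "I", hist1),
                               cbind(hla_class = "II", hist2)),
                         file.path(out, "length_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(assignments,
                         file.path(out, "allotype_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log <<- stage_log(log, "immunopeptidome", dedup$n_retained,
                        " records at FDR <= ", config$fdr_max, "; ",
                        length(dedup$pooled[["I"]]), " unique class I, ",
                        length(dedup$pooled[["II"]]),
                        " unique class II; ", nrow(observed),
                        " observed neoantigen match(es)")
      list(dedup = dedup, hist = list(I = hist1, II = hist2),
           assignments = assignments, observed = observed)
    })

  if (!is.null(config$sbs_catalogs) && !is.null(config$sbs_reference)) {
    results$signatures <- run_stage("signatures", character(), function() {
      catalogs <- read_sbs_matrix(config$sbs_catalogs)
      reference <- read_sbs_matrix(config$sbs_reference)
      extracted <- extract_signatures(catalogs, k = config$sbs_k,
                                      seed = config$seed)
      matches <- match_reference(extracted, reference)
      refit <- sapply(seq_len(ncol(catalogs)), function(j) {
        refit_exposures(catalogs[, j], reference)
      })
      colnames(refit) <- colnames(catalogs)
      utils::write.table(matches, file.path(out, "signature_matches.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(signature = rownames(refit), refit,
                                    check.names = FALSE),
                         file.path(out, "signature_exposures.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log <<- stage_log(log, "signatures", "extracted ", config$sbs_k,
                        " signatures; best matches: ",
                        paste(matches$best_match, collapse = ", "))
      list(extracted = extracted, matches = matches, refit = refit)
    })
  }

  writeLines(log, file.path(out, "run.log"))
  outputs <- sort(setdiff(list.files(out, recursive = TRUE),
                          c("manifest.json", "run.log")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("neoscan")),
    seed = config$seed,
    thresholds = unclass(config$thresholds),
    max_nM = config$max_nM, fdr_max = config$fdr_max,
    failed_stages = failed,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest, log = log)))
}
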