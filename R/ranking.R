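# Candidate scoring and per-allotype/per-length ranked tables. The rank
# score is the printed formula implemented literally:
#
#   score = binding score + fold change
#           + variant expression x fold change + tumour VAF / 2
#
# where binding score is 1 / (median mutant affinity in nM) and fold
# change is the unrounded agretopicity (wildtype / mutant median
# affinity). Expression enters in linear TPM and VAF as a fraction.

#' Neoantigen rank score
#'
#' `1/mt_nM + wt_nM/mt_nM + gene_tpm * (wt_nM/mt_nM) + vaf/2`, vectorised.
#' The score is strictly decreasing in the mutant affinity and strictly
#' increasing in wildtype affinity, expression and VAF.
#'
#' @param mt_nM Positive mutant median affinity (nM).
#' @param wt_nM Positive wildtype median affinity (nM).
#' @param gene_tpm Gene expression in transcripts per million (>= 0).
#' @param vaf Tumour variant allele fraction in \[0, 1\].
#' @return Numeric score.
#' @export
#' @examples
#' candidate_score(100, 100, 0, 0)  # 1.01
candidate_score <- function(mt_nM, wt_nM, gene_tpm, vaf) {
  if (any(mt_nM <= 0) || any(wt_nM <= 0)) {
    stop("affinities must be positive")
  }
  if (any(gene_tpm < 0)) stop("gene_tpm must be non-negative")
  if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]")
  fold <- wt_nM / mt_nM
  1 / mt_nM + fold + gene_tpm * fold + vaf / 2
}

#' Keep candidates below the binding-affinity cutoff
#'
#' @param candidates Candidate data frame with an `mt_nM` column.
#' @param max_nM Strict upper bound on mutant median affinity
#'   (default 500 nM; a candidate at exactly 500 is removed).
#' @return The surviving subset, order preserved.
#' @export
filter_binders <- function(candidates, max_nM = 500) {
  out <- candidates[candidates$mt_nM < max_nM, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score candidates from mutation windows and binding predictors
#'
#' For every window whose length matches an allotype's class (class I
#' allotypes at the class I lengths, DRB1 allotypes at the class II
#' length), predicts mutant and wildtype consensus affinities, computes
#' agretopicity and the rank score.
#'
#' @param windows Window data frame from [mutanome_windows()] (needs
#'   `sequence`, `wildtype_sequence`, `length`, `gene`, `mutation`,
#'   `vaf`, `gene_tpm`).
#' @param predictors List of `binding_predictor` objects.
#' @param class1_allotypes,class2_allotypes Character vectors of donor
#'   allotypes. Class II is restricted to DRB1: any other class II locus
#'   is rejected.
#' @param class1_lengths Class I lengths (default 8:11).
#' @param class2_length Class II length (default 15).
#' @return Candidate data frame (one row per window x allotype) with
#'   Table-style columns plus `score`.
#' @export
predict_candidates <- function(windows, predictors,
                               class1_allotypes, class2_allotypes = character(),
                               class1_lengths = 8:11, class2_length = 15L) {
  bad2 <- class2_allotypes[!grepl("DRB1", class2_allotypes)]
  if (length(bad2) > 0L) {
    stop("class II is restricted to DRB1 allotypes; got: ",
         paste(bad2, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    L <- windows$length[i]
    allos <- c(if (L %in% class1_lengths) class1_allotypes,
               if (L %in% class2_length) class2_allotypes)
    for (allo in allos) {
      mt <- consensus_affinity(windows$sequence[i], allo, predictors)
      wt <- consensus_affinity(windows$wildtype_sequence[i], allo,
                               predictors)
      agr <- agretopicity(wt$median_nM, mt$median_nM)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = windows$gene[i],
        wt_peptide = windows$wildtype_sequence[i],
        mt_peptide = windows$sequence[i],
        mutation = windows$mutation[i],
        length = L, allotype = allo,
        wt_nM = wt$median_nM, mt_nM = mt$median_nM,
        agretopicity_ratio = agr$ratio,
        agretopicity = agr$ratio_rounded,
        gene_tpm = windows$gene_tpm[i], vaf = windows$vaf[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  out$score <- candidate_score(out$mt_nM, out$wt_nM, out$gene_tpm, out$vaf)
  rownames(out) <- NULL
  out
}

#' Split candidates into ranked per-allotype / per-length tables
#'
#' One table per (allotype, length) pair, rows sorted by descending
#' score; ties broken by lower mutant affinity, then lexicographic
#' mutant peptide, making the ordering fully deterministic. `rank` is the
#' 1-based row position.
#'
#' @param candidates Candidate data frame (needs `allotype`, `length`,
#'   `score`, `mt_nM`, `mt_peptide`).
#' @return Named list of data frames keyed `"<allotype>|<length>"`,
#'   ordered by allotype then length.
#' @export
rank_tables <- function(candidates) {
  if (nrow(candidates) == 0L) return(structure(list(), names = character()))
  key <- paste0(candidates$allotype, "|", candidates$length)
  groups <- split(seq_len(nrow(candidates)), key)
  groups <- groups[order(names(groups), method = "radix")]
  lapply(groups, function(idx) {
    tab <- candidates[idx, , drop = FALSE]
    ord <- order(-tab$score, tab$mt_nM, tab$mt_peptide, method = "radix")
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    tab
  })
}

#' Write ranked tables and a combined top-k summary
#'
#' One TSV per (allotype, length) table, plus `top_candidates.tsv`
#' holding the top `top_k` rows of each table.
#'
#' @param tables Named list from [rank_tables()].
#' @param dir Output directory (created if needed).
#' @param top_k Rows per table in the combined summary (default 10).
#' @return Invisibly, the combined summary data frame.
#' @export
write_rank_tables <- function(tables, dir, top_k = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tops <- list()
  for (key in names(tables)) {
    tab <- tables[[key]]
    slug <- gsub("[^A-Za-z0-9]+", "_", key)
    utils::write.table(tab, file.path(dir, paste0("ranked_", slug, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tops[[key]] <- utils::head(tab, top_k)
  }
  combined <- if (length(tops) > 0L) do.call(rbind, tops) else data.frame()
  rownames(combined) <- NULL
  utils::write.table(combined, file.path(dir, "top_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(combined)
}
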