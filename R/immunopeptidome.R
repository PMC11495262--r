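# Immunopeptidome summarization and direct neoantigen detection:
# FDR filtering and per-class deduplication of eluted-peptide
# identifications, length distributions, best-PSSM allotype assignment,
# and exact-substring matching of mutation-spanning peptides against the
# mutanome with a reference-proteome absence requirement.

#' Read an eluted-peptide identification table
#'
#' Tab-separated peptide-level output of a spectral search engine:
#' columns `sequence`, `sample`, `hla_class` (`"I"` or `"II"`), `fdr`.
#'
#' @param path Path to the TSV.
#' @return Data frame of eluted-peptide records.
#' @export
read_peptide_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sequence", "sample", "hla_class", "fdr")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("peptide table lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' FDR-filter and deduplicate eluted peptides
#'
#' Retains records at or below the FDR cutoff, then reduces to distinct
#' sequences per HLA class, per sample and pooled across samples. The
#' same sequence identified several times in one sample counts once; a
#' sequence seen in both classes counts once per class.
#'
#' @param records Eluted-peptide data frame (see [read_peptide_table()]).
#' @param fdr_max FDR cutoff, inclusive (default 0.01).
#' @return List with `per_sample` (distinct (sample, hla_class,
#'   sequence) rows), `pooled` (named list of character vectors of unique
#'   sequences per class) and `n_retained` (record count after the FDR
#'   cut, before deduplication).
#' @export
dedupe_peptides <- function(records, fdr_max = 0.01) {
  kept <- records[records$fdr <= fdr_max, , drop = FALSE]
  per_sample <- unique(kept[, c("sample", "hla_class", "sequence")])
  per_sample <- per_sample[order(per_sample$sample, per_sample$hla_class,
                                 per_sample$sequence, method = "radix"), ,
                           drop = FALSE]
  rownames(per_sample) <- NULL
  pooled <- lapply(split(kept$sequence, kept$hla_class),
                   function(x) sort(unique(x)))
  list(per_sample = per_sample, pooled = pooled, n_retained = nrow(kept))
}

#' Peptide length distribution
#'
#' @param peptides Character vector of peptide sequences.
#' @param bins Optional integer range of lengths to report (zero-filled);
#'   defaults to the observed min..max.
#' @return Data frame with columns `length` and `count`; counts sum to
#'   `length(peptides)`.
#' @export
length_distribution <- function(peptides, bins = NULL) {
  lens <- nchar(peptides)
  if (is.null(bins)) {
    if (length(lens) == 0L) {
      return(data.frame(length = integer(), count = integer()))
    }
    bins <- seq(min(lens), max(lens))
  }
  counts <- vapply(bins, function(L) sum(lens == L), integer(1))
  data.frame(length = as.integer(bins), count = counts)
}

#' Assign peptides to HLA allotypes by best PSSM score
#'
#' A deliberate simplification of mixture-model motif deconvolution: each
#' peptide goes to the donor allotype whose PSSM (of matching length)
#' gives the maximal summed score. Ties break to the lexicographically
#' first allotype name. Peptides whose length no PSSM covers are
#' reported unassigned.
#'
#' @param peptides Character vector of peptide sequences.
#' @param donor_pssms List of `pssm` objects for the donor's typed
#'   allotypes.
#' @return Data frame with columns `sequence`, `length`, `allotype`
#'   (`NA` when unassigned), `score`, `margin` (score lead over the
#'   runner-up; `Inf` when only one allotype covers the length).
#' @export
assign_allotypes <- function(peptides, donor_pssms) {
  by_len <- split(donor_pssms,
                  vapply(donor_pssms, `[[`, integer(1), "length"))
  n <- length(peptides)
  allotype <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  margin <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    L <- as.character(nchar(peptides[i]))
    cand <- by_len[[L]]
    if (is.null(cand)) next
    names <- vapply(cand, `[[`, "", "allotype")
    ord <- order(names, method = "radix")  # lexicographic tie-break
    cand <- cand[ord]
    names <- names[ord]
    scores <- vapply(cand, function(p) pssm_score(peptides[i], p),
                     numeric(1))
    best <- which.max(scores)  # first max wins the tie
    allotype[i] <- names[best]
    score[i] <- scores[best]
    margin[i] <- if (length(scores) > 1L) {
      scores[best] - max(scores[-best])
    } else Inf
  }
  data.frame(sequence = peptides, length = nchar(peptides),
             allotype = allotype, score = score, margin = margin,
             stringsAsFactors = FALSE)
}

#' Fraction of an allotype's assigned peptides at a given length
#'
#' @param assignments Data frame from [assign_allotypes()].
#' @param allotype Allotype name (must appear in the assignments).
#' @param length Peptide length of interest.
#' @return Fraction in \[0, 1\].
#' @export
fraction_at_length <- function(assignments, allotype, length) {
  mine <- assignments[!is.na(assignments$allotype) &
                        assignments$allotype == allotype, , drop = FALSE]
  if (nrow(mine) == 0L) {
    stop("no peptides assigned to allotype ", allotype)
  }
  sum(mine$length == length) / nrow(mine)
}

# all start positions of fixed pattern in subject (1-based)
substring_starts <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Detect directly observed neoantigens in an immunopeptidome
#'
#' A peptide is reported as an observed neoantigen when it (a) occurs as
#' an exact substring of a mutated protein, (b) spans the mutated
#' residue, and (c) does not occur as a substring of any reference
#' proteome entry. Matching is exact: isoleucine and leucine are
#' distinct, but matches that coincide with the reference only under
#' I/L equivalence are flagged in `il_ambiguous` (mass spectrometry
#' cannot distinguish the two residues).
#'
#' @param peptides Character vector of (deduplicated) peptide sequences.
#' @param mutanome Data frame from [build_mutanome()].
#' @param proteome Reference proteome data frame from [read_proteome()].
#' @return Data frame of observed neoantigens: `sequence`, `protein_id`,
#'   `mutanome_id`, `wt_aa`, `residue_pos`, `mt_aa`,
#'   `mut_pos_in_peptide`, `il_ambiguous`.
#' @export
match_mutanome <- function(peptides, mutanome, proteome) {
  empty <- data.frame(sequence = character(), protein_id = character(),
                      mutanome_id = character(), wt_aa = character(),
                      residue_pos = integer(), mt_aa = character(),
                      mut_pos_in_peptide = integer(),
                      il_ambiguous = logical())
  if (length(peptides) == 0L || nrow(mutanome) == 0L) return(empty)
  # concatenated reference with a non-residue separator: peptides cannot
  # span entries, so one fixed-string search covers the whole proteome
  ref_cat <- paste(proteome$sequence, collapse = "#")
  ref_cat_il <- gsub("I", "L", ref_cat, fixed = TRUE)
  rows <- list()
  for (pep in unique(peptides)) {
    if (grepl(pep, ref_cat, fixed = TRUE)) next  # present in reference
    il_flag <- grepl(gsub("I", "L", pep, fixed = TRUE), ref_cat_il,
                     fixed = TRUE)
    for (j in seq_len(nrow(mutanome))) {
      for (s in substring_starts(pep, mutanome$sequence[j])) {
        e <- s + nchar(pep) - 1L
        rp <- mutanome$residue_pos[j]
        if (rp < s || rp > e) next  # does not span the mutated residue
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = pep,
          protein_id = mutanome$protein_id[j],
          mutanome_id = mutanome$mutanome_id[j],
          wt_aa = mutanome$wt_aa[j], residue_pos = rp,
          mt_aa = mutanome$mt_aa[j],
          mut_pos_in_peptide = rp - s + 1L,
          il_ambiguous = il_flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$sequence, out$mutanome_id, out$mut_pos_in_peptide,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
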