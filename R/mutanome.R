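# Mutanome construction: apply protein-level missense variants to a
# reference proteome and enumerate mutation-spanning peptide windows at
# class I (8-11) and class II (15) lengths. Residue coordinates are
# 1-based throughout.

#' Read a protein FASTA into a proteome table
#'
#' Headers are parsed as `protein_id` up to the first whitespace; a
#' `gene=SYMBOL` token in the description, if present, fills the `gene`
#' column.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data frame with columns `protein_id`, `gene`, `sequence`.
#' @export
read_proteome <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  gene <- rep(NA_character_, length(headers))
  hit <- regmatches(headers, regexpr("gene=\\S+", headers))
  has <- grepl("gene=", headers, fixed = TRUE)
  gene[has] <- sub("^gene=", "", hit)
  data.frame(protein_id = ids, gene = gene,
             sequence = as.character(set), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a proteome or mutanome table as FASTA
#'
#' @param proteome Data frame with `protein_id` (or `mutanome_id`) and
#'   `sequence` columns; a `gene` column, if present, is appended to the
#'   header as `gene=SYMBOL`.
#' @param path Output FASTA path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  id_col <- if ("mutanome_id" %in% names(proteome)) "mutanome_id" else
    "protein_id"
  headers <- proteome[[id_col]]
  if ("gene" %in% names(proteome)) {
    has <- !is.na(proteome$gene)
    headers[has] <- paste0(headers[has], " gene=", proteome$gene[has])
  }
  set <- Biostrings::AAStringSet(proteome$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a missense variant table
#'
#' Tab-separated with columns `protein_id`, `gene`, `residue_pos`,
#' `wt_aa`, `mt_aa`, `vaf`, `tpm`.
#'
#' @param path Path to the TSV.
#' @return Data frame of missense variants.
#' @export
read_missense_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "gene", "residue_pos", "wt_aa", "mt_aa",
            "vaf", "tpm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("missense table lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

#' Apply a single missense substitution to a protein sequence
#'
#' The stated wildtype residue is checked against the reference sequence;
#' a mismatch is a consistency error naming the protein and position.
#' Only single-residue substitutions are modeled; frameshift or stop-gain
#' consequences must be filtered out upstream.
#'
#' @param sequence Reference amino-acid sequence.
#' @param residue_pos 1-based position of the substitution.
#' @param wt_aa,mt_aa Single wildtype / mutant residues (must differ).
#' @param protein_id Identifier used in error messages.
#' @return The mutated sequence (same length).
#' @export
#' @examples
#' apply_missense("MKDAKLGGVIYQ", 7, "G", "R")  # "MKDAKLRGVIYQ"
apply_missense <- function(sequence, residue_pos, wt_aa, mt_aa,
                           protein_id = "protein") {
  check_aa_string(sequence, "protein sequence")
  if (!wt_aa %in% aa_alphabet() || !mt_aa %in% aa_alphabet()) {
    stop("wt_aa and mt_aa must be single standard amino acids")
  }
  if (wt_aa == mt_aa) stop("wt_aa and mt_aa must differ (missense)")
  n <- nchar(sequence)
  if (residue_pos < 1L || residue_pos > n) {
    stop("residue_pos ", residue_pos, " outside ", protein_id,
         " (length ", n, ")")
  }
  found <- substr(sequence, residue_pos, residue_pos)
  if (found != wt_aa) {
    stop("wildtype mismatch in ", protein_id, " at residue ", residue_pos,
         ": expected ", wt_aa, ", reference has ", found)
  }
  paste0(substr(sequence, 1L, residue_pos - 1L), mt_aa,
         substr(sequence, residue_pos + 1L, n))
}

#' Enumerate mutation-spanning peptide windows
#'
#' For each requested length L, every window of length L that lies fully
#' inside the protein and covers the mutated residue is emitted, paired
#' with its wildtype sequence. Windows that would extend past either
#' terminus are omitted (fixed-length predictor inputs are never padded
#' or truncated). An interior mutation therefore yields exactly L windows
#' of length L.
#'
#' @param mutated Mutated protein sequence.
#' @param wildtype Reference protein sequence (same length).
#' @param residue_pos 1-based position of the mutated residue.
#' @param lengths Integer vector of window lengths (default `c(8:11, 15)`:
#'   class I 8-11mers and class II 15mers).
#' @param protein_id Identifier carried through to the output.
#' @return Data frame with one row per window: `protein_id`, `length`,
#'   `start`, `end`, `mut_pos_in_peptide`, `sequence`,
#'   `wildtype_sequence`.
#' @export
enumerate_mutation_windows <- function(mutated, wildtype, residue_pos,
                                       lengths = c(8:11, 15L),
                                       protein_id = "protein") {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  n <- nchar(mutated)
  if (nchar(wildtype) != n) {
    stop("mutated and wildtype sequences differ in length")
  }
  rows <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    start_min <- max(1L, residue_pos - L + 1L)
    start_max <- min(residue_pos, n - L + 1L)
    if (start_max < start_min) next  # protein too short for this L
    for (s in start_min:start_max) {
      e <- s + L - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = protein_id, length = L, start = s, end = e,
        mut_pos_in_peptide = residue_pos - s + 1L,
        sequence = substr(mutated, s, e),
        wildtype_sequence = substr(wildtype, s, e),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(protein_id = character(), length = integer(),
                      start = integer(), end = integer(),
                      mut_pos_in_peptide = integer(),
                      sequence = character(),
                      wildtype_sequence = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a mutanome from a proteome and a missense variant table
#'
#' One singly-mutated protein record per variant. Two variants on the
#' same protein give two records, each carrying exactly one mutation
#' (proximal-variant phasing is out of scope). Records are ordered by
#' (protein_id, residue_pos, mt_aa) and identified as
#' `proteinID_p.<Wt><Pos><Mt>`.
#'
#' @param proteome Data frame from [read_proteome()].
#' @param variants Missense table (see [read_missense_table()]).
#' @return Data frame with columns `mutanome_id`, `protein_id`, `gene`,
#'   `residue_pos`, `wt_aa`, `mt_aa`, `vaf`, `gene_tpm`, `sequence`
#'   (mutated), `wildtype_sequence`.
#' @export
build_mutanome <- function(proteome, variants) {
  if (nrow(variants) == 0L) {
    return(data.frame(mutanome_id = character(), protein_id = character(),
                      gene = character(), residue_pos = integer(),
                      wt_aa = character(), mt_aa = character(),
                      vaf = numeric(), gene_tpm = numeric(),
                      sequence = character(),
                      wildtype_sequence = character()))
  }
  missing <- setdiff(unique(variants$protein_id), proteome$protein_id)
  if (length(missing) > 0L) {
    stop("missense variants reference unknown protein(s): ",
         paste(missing, collapse = ", "))
  }
  idx <- match(variants$protein_id, proteome$protein_id)
  wt_seq <- proteome$sequence[idx]
  mut_seq <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    mut_seq[i] <- apply_missense(wt_seq[i], variants$residue_pos[i],
                                 variants$wt_aa[i], variants$mt_aa[i],
                                 variants$protein_id[i])
  }
  out <- data.frame(
    mutanome_id = paste0(variants$protein_id, "_p.", variants$wt_aa,
                         variants$residue_pos, variants$mt_aa),
    protein_id = variants$protein_id,
    gene = variants$gene,
    residue_pos = as.integer(variants$residue_pos),
    wt_aa = variants$wt_aa, mt_aa = variants$mt_aa,
    vaf = variants$vaf, gene_tpm = variants$tpm,
    sequence = mut_seq, wildtype_sequence = wt_seq,
    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$residue_pos, out$mt_aa,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate windows for every mutanome entry
#'
#' Convenience wrapper running [enumerate_mutation_windows()] over a
#' mutanome, carrying gene, VAF and expression through to each window.
#'
#' @param mutanome Data frame from [build_mutanome()].
#' @param lengths Window lengths (default `c(8:11, 15)`).
#' @return Window data frame with mutanome annotation columns.
#' @export
mutanome_windows <- function(mutanome, lengths = c(8:11, 15L)) {
  parts <- lapply(seq_len(nrow(mutanome)), function(i) {
    w <- enumerate_mutation_windows(mutanome$sequence[i],
                                    mutanome$wildtype_sequence[i],
                                    mutanome$residue_pos[i],
                                    lengths = lengths,
                                    protein_id = mutanome$protein_id[i])
    if (nrow(w) == 0L) return(NULL)
    w$mutanome_id <- mutanome$mutanome_id[i]
    w$gene <- mutanome$gene[i]
    w$mutation <- paste0(mutanome$wt_aa[i], "/", mutanome$mt_aa[i])
    w$vaf <- mutanome$vaf[i]
    w$gene_tpm <- mutanome$gene_tpm[i]
    w
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    return(data.frame())
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
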