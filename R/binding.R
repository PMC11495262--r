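# Peptide-HLA binding: synthetic PSSM predictors behind a pluggable
# predictor interface, consensus (median) aggregation across predictors,
# and agretopicity. The PSSM predictors are deliberately simple test
# plumbing standing in for external binding algorithms: a fixed monotone
# squashing maps motif score to an affinity in (1, 50000) nM, so higher
# motif score always means stronger (lower nM) predicted binding.

# fixed constants of the synthetic predictor (non-physiological plumbing)
AFFINITY_CEILING_NM <- 50000
SQUASH_SCALE <- 4

#' Construct a position-specific scoring matrix
#'
#' @param allotype HLA allotype name, e.g. `"HLA-A*03:01"`.
#' @param weights Numeric `length x 20` matrix of per-position log-odds
#'   scores; columns must be named by [aa_alphabet()].
#' @return A `pssm` object.
#' @export
make_pssm <- function(allotype, weights) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 20L || !identical(colnames(weights), aa_alphabet())) {
    stop("weights must have 20 columns named by aa_alphabet()")
  }
  if (any(!is.finite(weights))) stop("PSSM weights must be finite")
  structure(list(allotype = allotype, length = nrow(weights),
                 weights = weights),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM:", x$allotype, "length", x$length, "\n")
  invisible(x)
}

#' Random anchor-style PSSM
#'
#' Generates a motif with a few strong anchor positions (as real HLA
#' motifs have) over a weak random background. Used by the synthetic-data
#' generator and the tests.
#'
#' @param allotype Allotype name.
#' @param length Peptide length the matrix scores.
#' @param n_anchors Number of anchor positions (default 2).
#' @param strength Log-odds weight of the preferred residue at each
#'   anchor (default 3).
#' @param seed Integer seed; the matrix is deterministic given it.
#' @return A `pssm` object.
#' @export
random_pssm <- function(allotype, length, n_anchors = 2, strength = 3,
                        seed = 1) {
  set.seed(seed)
  w <- matrix(stats::rnorm(length * 20, sd = 0.25), nrow = length,
              dimnames = list(NULL, aa_alphabet()))
  anchors <- sample.int(length, min(n_anchors, length))
  for (a in anchors) {
    w[a, sample.int(20L, 1L)] <- strength
  }
  make_pssm(allotype, w)
}

#' Sum of PSSM position scores for a peptide
#'
#' @param peptide Amino-acid string of the PSSM's length.
#' @param pssm A `pssm` object.
#' @return Numeric motif score.
#' @export
pssm_score <- function(peptide, pssm) {
  stopifnot(inherits(pssm, "pssm"))
  check_aa_string(peptide, "peptide")
  if (nchar(peptide) != pssm$length) {
    stop("peptide length ", nchar(peptide), " does not match PSSM length ",
         pssm$length)
  }
  aa <- strsplit(peptide, "")[[1]]
  sum(pssm$weights[cbind(seq_along(aa), match(aa, aa_alphabet()))])
}

#' Predicted binding affinity of a peptide under a PSSM
#'
#' Maps the summed motif score s through a fixed logistic squashing
#' sigma(s) = 1 / (1 + exp(-s / 4)) to `nM = 50000^(1 - sigma(s))`, so the
#' affinity is strictly decreasing in the motif score and bounded in
#' (1, 50000) nM.
#'
#' @inheritParams pssm_score
#' @return Predicted affinity in nM.
#' @export
predict_affinity <- function(peptide, pssm) {
  s <- pssm_score(peptide, pssm)
  sigma <- 1 / (1 + exp(-s / SQUASH_SCALE))
  AFFINITY_CEILING_NM^(1 - sigma)
}

#' Consensus affinity: the median across algorithms
#'
#' @param per_algorithm_nM Non-empty numeric vector of positive
#'   per-algorithm affinities in nM.
#' @return The statistical median (mean of central pair for even counts).
#' @export
consensus_median <- function(per_algorithm_nM) {
  if (length(per_algorithm_nM) == 0L) {
    stop("at least one per-algorithm affinity is required")
  }
  if (any(per_algorithm_nM <= 0)) stop("affinities must be positive")
  stats::median(per_algorithm_nM)
}

#' Agretopicity: wildtype / mutant affinity ratio
#'
#' The relative increase in predicted binding affinity of the mutant
#' peptide over its wildtype counterpart. Values above 1 mean the
#' mutation improves binding. The unrounded ratio feeds the rank score;
#' the half-up-rounded integer is what candidate tables report.
#'
#' @param wt_nM,mt_nM Positive median affinities in nM.
#' @return List with `wt_nM`, `mt_nM`, `ratio`, `ratio_rounded`.
#' @export
#' @examples
#' agretopicity(9940, 74)$ratio_rounded  # 134
agretopicity <- function(wt_nM, mt_nM) {
  if (any(wt_nM <= 0) || any(mt_nM <= 0)) {
    stop("affinities must be positive")
  }
  ratio <- wt_nM / mt_nM
  list(wt_nM = wt_nM, mt_nM = mt_nM, ratio = ratio,
       ratio_rounded = round_half_up(ratio))
}

# ---- pluggable predictor interface ------------------------------------

#' Build a synthetic PSSM-based binding predictor
#'
#' A predictor is a named object exposing affinities for any
#' (peptide, allotype) whose length it has a matrix for. `jitter_sd`
#' perturbs the PSSM weights once at construction (deterministically
#' under `jitter_seed`), so several predictors built from the same PSSM
#' set disagree the way independent algorithms do; the consensus median
#' then has something to aggregate.
#'
#' @param name Algorithm name reported in output tables.
#' @param pssm_set List of `pssm` objects (any order; looked up by
#'   allotype and peptide length).
#' @param jitter_sd Standard deviation of weight perturbation (default 0).
#' @param jitter_seed Seed for the perturbation.
#' @return A `binding_predictor` object.
#' @export
pssm_predictor <- function(name, pssm_set, jitter_sd = 0, jitter_seed = 1) {
  stopifnot(all(vapply(pssm_set, inherits, logical(1), "pssm")))
  if (jitter_sd > 0) {
    set.seed(jitter_seed)
    pssm_set <- lapply(pssm_set, function(p) {
      w <- p$weights + matrix(stats::rnorm(length(p$weights),
                                           sd = jitter_sd),
                              nrow = nrow(p$weights))
      colnames(w) <- aa_alphabet()
      make_pssm(p$allotype, w)
    })
  }
  keys <- vapply(pssm_set, function(p) paste0(p$allotype, "|", p$length), "")
  names(pssm_set) <- keys
  structure(list(name = name, pssms = pssm_set),
            class = "binding_predictor")
}

#' Predict affinity with one predictor
#'
#' @param predictor A `binding_predictor`.
#' @param peptide Amino-acid string.
#' @param allotype Allotype name.
#' @return Affinity in nM, or `NA` when the predictor has no matrix for
#'   this allotype and peptide length.
#' @export
predictor_affinity <- function(predictor, peptide, allotype) {
  stopifnot(inherits(predictor, "binding_predictor"))
  key <- paste0(allotype, "|", nchar(peptide))
  p <- predictor$pssms[[key]]
  if (is.null(p)) return(NA_real_)
  predict_affinity(peptide, p)
}

#' Consensus affinity of a peptide across registered predictors
#'
#' @param peptide Amino-acid string.
#' @param allotype Allotype name.
#' @param predictors List of `binding_predictor` objects.
#' @return List with `per_algorithm_nM` (named by algorithm) and
#'   `median_nM`.
#' @export
consensus_affinity <- function(peptide, allotype, predictors) {
  vals <- vapply(predictors, predictor_affinity, numeric(1),
                 peptide = peptide, allotype = allotype)
  names(vals) <- vapply(predictors, `[[`, "", "name")
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) {
    stop("no predictor covers allotype ", allotype, " at length ",
         nchar(peptide))
  }
  list(per_algorithm_nM = vals, median_nM = consensus_median(vals))
}

# ---- PSSM serialization ------------------------------------------------

#' Write a PSSM as a tab-separated matrix
#'
#' First line is a `# allotype=<name> length=<L>` header; then a header
#' row of the 20 amino acids and one row per peptide position.
#'
#' @param pssm A `pssm` object.
#' @param path Output path.
#' @export
write_pssm <- function(pssm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# allotype=%s length=%d", pssm$allotype,
                     pssm$length), con)
  writeLines(paste(aa_alphabet(), collapse = "\t"), con)
  utils::write.table(format(pssm$weights, digits = 10, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#'
#' @param path Path to the matrix file.
#' @return A `pssm` object.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines[1],
                  regexec("# allotype=(\\S+) length=(\\d+)", lines[1]))[[1]]
  if (length(m) != 3L) stop("malformed PSSM header in ", path)
  w <- as.matrix(utils::read.table(text = lines[-(1:2)], sep = "\t"))
  colnames(w) <- aa_alphabet()
  pssm <- make_pssm(m[2], w)
  if (pssm$length != as.integer(m[3])) {
    stop("PSSM header length disagrees with matrix rows in ", path)
  }
  pssm
}

#' Write / read a directory of PSSMs
#'
#' One file per (allotype, length), named from a filesystem-safe slug of
#' the allotype.
#'
#' @param pssm_set List of `pssm` objects.
#' @param dir Directory (created if needed).
#' @return `write_pssm_set`: invisibly, the file paths;
#'   `read_pssm_set`: the list of `pssm` objects.
#' @export
write_pssm_set <- function(pssm_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(pssm_set, function(p) {
    slug <- gsub("[^A-Za-z0-9]+", "_", p$allotype)
    file.path(dir, sprintf("pssm_%s_L%d.tsv", slug, p$length))
  }, "")
  for (i in seq_along(pssm_set)) write_pssm(pssm_set[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_pssm_set
#' @export
read_pssm_set <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^pssm_.*\\.tsv$",
                           full.names = TRUE))
  lapply(paths, read_pssm)
}
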