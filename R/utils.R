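# Shared helpers: amino-acid alphabet, rounding, chromosome ordering,
# cosine similarity, seed fan-out.

#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes in alphabetical order. This is the column
#' order of every PSSM in the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Round half away from zero
#'
#' Conventional "round half up" for positive values, unlike [base::round()]
#' which rounds half to even. Used for integer agretopicity in table output.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Cosine similarity between two vectors
#'
#' @param a,b Numeric vectors of equal length, not both zero.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}

# Natural chromosome rank: 1..22, X, Y, MT (with or without "chr" prefix),
# then unknown contigs lexicographically after.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", as.character(chrom))
  rank <- suppressWarnings(as.numeric(core))
  rank[core == "X"] <- 23
  rank[core == "Y"] <- 24
  rank[core %in% c("M", "MT")] <- 25
  rank
}

#' Order variant records by genomic coordinate
#'
#' Natural chromosome order (1-22, X, Y, MT, then unknown contigs
#' lexicographically), then position, then ref and alt alleles.
#'
#' @param df Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return Integer permutation suitable for subsetting `df`.
#' @export
genome_order <- function(df) {
  r <- chrom_rank(df$chrom)
  known <- !is.na(r)
  # unknown contigs sort after all known ones, lexicographically
  key_chrom <- ifelse(known, sprintf("%03d", r), paste0("z", df$chrom))
  order(key_chrom, df$pos, df$ref, df$alt, method = "radix")
}

#' Derive an independent seed for a named generator stream
#'
#' Fans one global seed out to per-generator streams so that adding a new
#' generator never perturbs the draws of existing ones. The derived seed is
#' a deterministic hash of the global seed and the stream name, kept below
#' 2^31.
#'
#' @param seed Integer global seed.
#' @param stream Character stream name, e.g. `"proteome"`.
#' @return A single integer seed.
#' @export
derive_stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 1000003L
  }
  as.integer((abs(seed) %% 65521L) * 32749L + h) %% .Machine$integer.max
}

# construct a vcfR object without attaching the vcfR package
new_vcfR <- function(meta, fix, gt) {
  methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
               meta = meta, fix = fix, gt = gt)
}

# validate a single amino-acid string; returns invisibly
check_aa_string <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || nchar(x) < 1L) {
    stop(what, " must be a single non-empty string")
  }
  bad <- setdiff(strsplit(x, "")[[1]], aa_alphabet())
  if (length(bad) > 0L) {
    stop(what, " contains non-standard residues: ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(x)
}
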