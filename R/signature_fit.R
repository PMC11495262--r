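# SBS96 mutational-signature analysis: trinucleotide-context counting on
# the pyrimidine strand, de novo extraction by Frobenius-loss NMF with
# seeded multiplicative-update restarts, cosine matching against a
# reference catalogue, and per-sample exposure refitting by non-negative
# least squares.

SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical SBS96 channel names
#'
#' Pyrimidine-centred substitutions `{C>A, C>G, C>T, T>A, T>C, T>G}` with
#' all 16 flanking-base combinations each, in the conventional order
#' (substitution class, then 5' base, then 3' base, alphabetical), e.g.
#' `"A[C>A]A"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  out <- character(0)
  for (sub in SBS_SUBS) {
    for (p5 in c("A", "C", "G", "T")) {
      for (p3 in c("A", "C", "G", "T")) {
        out <- c(out, paste0(p5, "[", sub, "]", p3))
      }
    }
  }
  out
}

revcomp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

#' Count single-base substitutions into the 96 trinucleotide channels
#'
#' Each SNV increments exactly one channel. Purine-centred substitutions
#' (reference A or G) are reverse-complemented to the pyrimidine strand,
#' including their flanking context.
#'
#' @param variants Data frame of single-nucleotide variants (`chrom`,
#'   `pos`, `ref`, `alt`; single-base alleles).
#' @param context_lookup Function `(chrom, pos) -> trinucleotide` giving
#'   the reference trinucleotide centred on the variant position.
#' @param sample Sample identifier attached to the catalog.
#' @return An `sbs_catalog`: named integer 96-vector (channel order of
#'   [sbs96_channels()]) with a `sample` attribute.
#' @export
count_sbs96 <- function(variants, context_lookup, sample = "sample") {
  counts <- stats::setNames(integer(96), sbs96_channels())
  if (nrow(variants) > 0L) {
    if (any(nchar(variants$ref) != 1L) || any(nchar(variants$alt) != 1L)) {
      stop("count_sbs96 accepts single-nucleotide substitutions only")
    }
    for (i in seq_len(nrow(variants))) {
      ref <- variants$ref[i]
      alt <- variants$alt[i]
      ctx <- context_lookup(variants$chrom[i], variants$pos[i])
      if (nchar(ctx) != 3L || substr(ctx, 2, 2) != ref) {
        stop("context at ", variants$chrom[i], ":", variants$pos[i],
             " is not a reference trinucleotide centred on the variant")
      }
      if (ref %in% c("A", "G")) {  # fold to the pyrimidine strand
        ref <- revcomp_base(ref)
        alt <- revcomp_base(alt)
        ctx <- paste0(revcomp_base(substr(ctx, 3, 3)), ref,
                      revcomp_base(substr(ctx, 1, 1)))
      }
      channel <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                        substr(ctx, 3, 3))
      counts[channel] <- counts[channel] + 1L
    }
  }
  structure(counts, sample = sample, class = c("sbs_catalog", "integer"))
}

# stack catalogs (list of 96-vectors or a matrix) into a 96 x n matrix
as_catalog_matrix <- function(catalogs) {
  if (is.matrix(catalogs)) {
    V <- catalogs
  } else if (is.list(catalogs)) {
    V <- do.call(cbind, lapply(catalogs, as.numeric))
    colnames(V) <- vapply(seq_along(catalogs), function(i) {
      s <- attr(catalogs[[i]], "sample")
      if (is.null(s)) paste0("sample", i) else s
    }, "")
  } else {
    V <- matrix(as.numeric(catalogs), ncol = 1)
  }
  if (nrow(V) != 96L) stop("catalogs must have 96 channels")
  rownames(V) <- sbs96_channels()
  V
}

# one multiplicative-update NMF run (Frobenius loss)
nmf_run <- function(V, k, seed, max_iter, tol) {
  set.seed(seed)
  m <- nrow(V); n <- ncol(V)
  scale <- sqrt(mean(V) / k)
  W <- matrix(stats::runif(m * k, 0, 2 * scale), m, k)
  H <- matrix(stats::runif(k * n, 0, 2 * scale), k, n)
  eps <- .Machine$double.eps
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% (H %*% t(H)) + eps)
    if (it %% 20L == 0L) {
      loss <- sum((V - W %*% H)^2)
      if (prev - loss < tol * max(prev, 1)) break
      prev <- loss
    }
  }
  loss <- sum((V - W %*% H)^2)
  list(W = W, H = H, loss = loss)
}

#' Extract de novo mutational signatures by NMF
#'
#' Non-negative factorization of the 96 x n catalog matrix minimising
#' Frobenius reconstruction error, via multiplicative updates over
#' several seeded random initialisations; the best restart is returned.
#' Signature columns are normalised to sum to 1 with the mass moved into
#' the exposures, so exposures are in mutation counts.
#'
#' @param catalogs List of `sbs_catalog` vectors, or a 96 x n matrix.
#' @param k Number of signatures to extract (1..96).
#' @param seed Base seed; restart r uses `seed + r - 1`.
#' @param restarts Number of random initialisations (default 10).
#' @param max_iter,tol Update iteration cap and relative loss tolerance.
#' @return A `signature_set` list: `signatures` (96 x k, columns sum
#'   to 1), `exposures` (k x n), `loss`, `k`.
#' @export
extract_signatures <- function(catalogs, k, seed = 1, restarts = 10,
                               max_iter = 2000, tol = 1e-10) {
  V <- as_catalog_matrix(catalogs)
  if (k < 1L) stop("k must be at least 1")
  if (k > 96L) stop("k cannot exceed the 96 channels")
  if (all(V == 0)) stop("all-zero catalogs: nothing to factorize")
  if (k > ncol(V)) {
    warning("k exceeds the number of samples; the factorization is ",
            "under-determined")
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- nmf_run(V, k, seed = seed + r - 1L, max_iter = max_iter,
                   tol = tol)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  colsum <- colSums(best$W)
  colsum[colsum == 0] <- 1
  W <- sweep(best$W, 2, colsum, "/")
  H <- sweep(best$H, 1, colsum, "*")
  # deterministic signature order: by total exposure, largest first
  ord <- order(-rowSums(H))
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  dimnames(W) <- list(sbs96_channels(), paste0("S", seq_len(k)))
  dimnames(H) <- list(paste0("S", seq_len(k)), colnames(V))
  structure(list(signatures = W, exposures = H, loss = best$loss, k = k),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set:", x$k, "signatures x", ncol(x$exposures),
      "samples; Frobenius loss", format(x$loss, digits = 4), "\n")
  invisible(x)
}

#' Match extracted signatures to a reference catalogue by cosine
#'
#' @param extracted A `signature_set`, or a 96 x k matrix of signatures.
#' @param reference 96 x K matrix of reference signatures with column
#'   names (columns need not be normalised; cosine is scale-free).
#' @return Data frame with one row per extracted signature: `extracted`,
#'   `best_match`, `cosine`.
#' @export
match_reference <- function(extracted, reference) {
  W <- if (inherits(extracted, "signature_set")) extracted$signatures else
    as.matrix(extracted)
  reference <- as.matrix(reference)
  if (nrow(W) != nrow(reference)) {
    stop("extracted and reference signatures differ in channel count")
  }
  if (is.null(colnames(reference))) {
    stop("reference columns must be named")
  }
  rows <- lapply(seq_len(ncol(W)), function(j) {
    sims <- apply(reference, 2, cosine_similarity, b = W[, j])
    best <- which.max(sims)
    data.frame(extracted = colnames(W)[j] %||% paste0("S", j),
               best_match = colnames(reference)[best],
               cosine = unname(sims[best]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit a catalog onto reference signatures by NNLS
#'
#' Non-negative least-squares projection of a single 96-channel catalog
#' onto a set of reference signature columns, normalised to proportions.
#'
#' @param catalog An `sbs_catalog` or 96-vector of counts (not all zero).
#' @param reference 96 x K matrix of reference signatures (named
#'   columns).
#' @return Named numeric vector of exposure proportions summing to 1.
#' @export
refit_exposures <- function(catalog, reference) {
  v <- as.numeric(catalog)
  reference <- as.matrix(reference)
  if (length(v) != nrow(reference)) {
    stop("catalog and reference signatures differ in channel count")
  }
  if (ncol(reference) < 1L) stop("reference subset must be non-empty")
  if (all(v == 0)) stop("all-zero catalog cannot be refitted")
  fit <- pracma::lsqnonneg(reference, v)
  x <- fit$x
  names(x) <- colnames(reference)
  x / sum(x)
}

#' Write / read a 96-row signature or catalog matrix as TSV
#'
#' Rows labelled by channel (e.g. `"A[C>T]A"`), one column per
#' signature or sample.
#'
#' @param mat Matrix with 96 rows.
#' @param path File path.
#' @return `read_sbs_matrix`: the matrix with channel rownames.
#' @export
write_sbs_matrix <- function(mat, path) {
  df <- data.frame(channel = sbs96_channels(), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sbs_matrix
#' @export
read_sbs_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$channel
  if (!identical(rownames(mat), sbs96_channels())) {
    stop("channel order in ", path, " is not the canonical SBS96 order")
  }
  mat
}
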