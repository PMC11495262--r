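test_that("the channel set is the canonical pyrimidine-centred 96", {
  ch <- sbs96_channels()
  expect_equal(length(ch), 96L)
  expect_equal(anyDuplicated(ch), 0L)
  expect_equal(ch[1], "A[C>A]A")
  expect_equal(ch[96], "T[T>G]T")
})

snv <- function(chrom, pos, ref, alt) {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("SNVs land in their trinucleotide channel, purines reverse-complemented", {
  ctx <- function(chrom, pos) c(`1:10` = "ACA", `1:20` = "TGT")[
    paste0(chrom, ":", pos)]
  cat1 <- count_sbs96(snv("1", 10, "C", "T"), ctx)
  expect_equal(unname(cat1["A[C>T]A"]), 1L)
  expect_equal(sum(cat1), 1L)
  # G>A in TGT is C>T in ACA on the pyrimidine strand
  cat2 <- count_sbs96(snv("1", 20, "G", "A"), ctx)
  expect_equal(unname(cat2["A[C>T]A"]), 1L)
  expect_error(count_sbs96(snv("1", 10, "CA", "T"), ctx),
               "single-nucleotide")
  expect_error(count_sbs96(snv("1", 10, "C", "T"),
                           function(chrom, pos) "AGA"),
               "centred")
})

test_that("counting conserves the SNV total and is a strand involution", {
  set.seed(71)
  n <- 960
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "",
                USE.NAMES = FALSE)
  ctx_map <- vapply(ref, function(b) paste0(sample(bases, 1), b,
                                            sample(bases, 1)), "",
                    USE.NAMES = FALSE)
  vars <- snv("1", seq_len(n), ref, alt)
  lookup <- function(chrom, pos) ctx_map[pos]
  catalog <- count_sbs96(vars, lookup)
  expect_equal(sum(catalog), n)
  # complementing every input leaves the catalog unchanged
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc3 <- function(s) paste0(comp[substr(s, 3, 3)], comp[substr(s, 2, 2)],
                            comp[substr(s, 1, 1)])
  vars_c <- snv("1", seq_len(n), unname(comp[ref]), unname(comp[alt]))
  ctx_c <- vapply(ctx_map, rc3, "", USE.NAMES = FALSE)
  lookup_c <- function(chrom, pos) ctx_c[pos]
  expect_equal(as.integer(count_sbs96(vars_c, lookup_c)),
               as.integer(catalog))
})

test_that("rank-1 extraction on identical samples recovers the mean spectrum", {
  set.seed(72)
  spec <- as.integer(rmultinom(1, 5000, rep(1 / 96, 96)))
  V <- cbind(spec, spec, spec)
  ext <- extract_signatures(V, k = 1, seed = 1, restarts = 3)
  expect_equal(ext$signatures[, 1], spec / sum(spec), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(sum(ext$signatures[, 1]), 1)
  # reproducible given (seed, restarts)
  ext2 <- extract_signatures(V, k = 1, seed = 1, restarts = 3)
  expect_equal(ext$signatures, ext2$signatures)
  expect_error(extract_signatures(matrix(0, 96, 3), k = 2), "all-zero")
  expect_error(extract_signatures(V, k = 97), "96")
})

test_that("reference matching finds exact, orthogonal and noisy copies", {
  ref <- generate_reference_signatures(4, seed = 73)
  # exact copy
  m <- match_reference(ref[, 2, drop = FALSE], ref)
  expect_equal(m$best_match, "SYNSIG2")
  expect_equal(m$cosine, 1)
  # one-hot spectra are orthogonal off-diagonal
  onehot <- diag(96)[, 1:2]
  colnames(onehot) <- c("e1", "e2")
  expect_equal(cosine_similarity(onehot[, 1], onehot[, 2]), 0)
  # multinomial-noisy copy still matches with high cosine
  set.seed(74)
  noisy <- as.numeric(rmultinom(1, 10000, ref[, 3]))
  m3 <- match_reference(matrix(noisy, ncol = 1), ref)
  expect_equal(m3$best_match, "SYNSIG3")
  expect_gte(m3$cosine, 0.95)
  expect_error(match_reference(matrix(1, 10, 1), ref), "channel")
})

test_that("NNLS refitting recovers exact and sampled mixtures", {
  ref <- generate_reference_signatures(2, seed = 75)
  exact <- as.numeric(ref %*% c(0.7, 0.3)) * 8000
  expect_equal(refit_exposures(exact, ref),
               c(SYNSIG1 = 0.7, SYNSIG2 = 0.3), tolerance = 1e-8)
  pure <- as.numeric(ref[, 1]) * 5000
  expect_equal(refit_exposures(pure, ref),
               c(SYNSIG1 = 1, SYNSIG2 = 0), tolerance = 1e-8)
  set.seed(76)
  sampled <- as.numeric(rmultinom(1, 10000,
                                  as.numeric(ref %*% c(0.6, 0.4))))
  fit <- refit_exposures(sampled, ref)
  expect_lt(max(abs(fit - c(0.6, 0.4))), 0.05)
  expect_error(refit_exposures(rep(0, 96), ref), "all-zero")
})

test_that("the two-signature refit beats any single-signature fit", {
  set.seed(77)
  ref <- generate_reference_signatures(2, seed = 78)
  v <- as.numeric(rmultinom(1, 10000, as.numeric(ref %*% c(0.5, 0.5))))
  fit <- refit_exposures(v, ref)
  recon_err <- function(w) sum((v - ref %*% (w * sum(v)))^2)
  # grid-search oracle over the 2-signature simplex
  grid <- seq(0, 1, by = 0.01)
  errs <- vapply(grid, function(a) recon_err(c(a, 1 - a)), numeric(1))
  # NNLS is scale-free; compare proportions at the grid optimum
  expect_lt(abs(fit[1] - grid[which.min(errs)]), 0.02)
  expect_lte(min(errs), recon_err(c(1, 0)))
  expect_lte(min(errs), recon_err(c(0, 1)))
})

test_that("SBS matrices round-trip through their TSV serialization", {
  ref <- generate_reference_signatures(3, seed = 79)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sbs_matrix(ref, path)
  back <- read_sbs_matrix(path)
  expect_equal(back, ref, tolerance = 1e-9)
})
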