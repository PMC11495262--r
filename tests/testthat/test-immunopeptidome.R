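test_that("deduplication is per class with an inclusive FDR cut", {
  rec <- data.frame(
    sequence = c("AAKLRGVI", "AAKLRGVI", "AAKLRGVI", "WYWYWYWYW",
                 "AAKLRGVI", "MMMMMMMMMMMMMMM"),
    sample = "s1",
    hla_class = c("I", "I", "I", "I", "II", "II"),
    fdr = c(0.001, 0.005, 0.01, 0.002, 0.004, 0.05),
    stringsAsFactors = FALSE)
  d <- dedupe_peptides(rec)
  # triplicate counted once; fdr exactly 0.01 retained (<=)
  expect_equal(d$pooled[["I"]], sort(c("AAKLRGVI", "WYWYWYWYW")))
  # the same sequence counts once per class
  expect_equal(d$pooled[["II"]], "AAKLRGVI")
  expect_equal(d$n_retained, 5L)
})

test_that("FDR-retained record count matches the predicate oracle", {
  set.seed(6)
  rec <- data.frame(sequence = replicate(10, paste(
    sample(aa_alphabet(), 9, TRUE), collapse = "")),
    sample = "s1", hla_class = "I",
    fdr = c(runif(8, 0, 0.01), 0.02, 0.03),
    stringsAsFactors = FALSE)
  d <- dedupe_peptides(rec)
  expect_equal(d$n_retained, sum(rec$fdr <= 0.01))
  expect_equal(d$n_retained, 8L)
})

test_that("length histograms count every peptide exactly once", {
  peps <- c(rep("AAKLRGVIW", 3), rep("MMMMMMMMMMMMMMM", 2))
  h <- length_distribution(peps)
  expect_equal(h$count[h$length == 9], 3L)
  expect_equal(h$count[h$length == 15], 2L)
  expect_equal(sum(h$count), length(peps))
  empty <- length_distribution(character(), bins = 8:11)
  expect_equal(empty$count, rep(0L, 4))
  # dedupe then histogram commutes with input permutation
  set.seed(31)
  rec <- data.frame(sequence = replicate(50, paste(
    sample(aa_alphabet(), sample(8:11, 1), TRUE), collapse = "")),
    sample = "s1", hla_class = "I", fdr = 0.001,
    stringsAsFactors = FALSE)
  h1 <- length_distribution(dedupe_peptides(rec)$pooled[["I"]])
  h2 <- length_distribution(
    dedupe_peptides(rec[sample.int(50), ])$pooled[["I"]])
  expect_equal(h1, h2)
})

test_that("peptides sampled from one motif are assigned back to it", {
  pssmA <- random_pssm("HLA-A*03:01", 9, strength = 5, seed = 41)
  pssmB <- random_pssm("HLA-B*07:02", 9, strength = 5, seed = 42)
  set.seed(43)
  peps <- replicate(40, neoscan:::sample_from_pssm(pssmA))
  asg <- assign_allotypes(peps, list(pssmA, pssmB))
  # strong-motif draws overwhelmingly score best under their own PSSM
  expect_gt(mean(asg$allotype == "HLA-A*03:01"), 0.9)
  expect_true(all(asg$margin[asg$allotype == "HLA-A*03:01"] >= 0))
})

test_that("assignment ties break lexicographically and length gaps are flagged", {
  p <- uniform_pssm("HLA-Z*01:01", 9)
  q <- uniform_pssm("HLA-A*03:01", 9)
  asg <- assign_allotypes("KLMNPQRST", list(p, q))
  expect_equal(asg$allotype, "HLA-A*03:01")  # identical scores -> first name
  asg8 <- assign_allotypes("KLMNPQRS", list(p, q))  # 8-mer, only 9-mer PSSMs
  expect_true(is.na(asg8$allotype))
})

test_that("per-allotype length fractions are computed over assigned peptides", {
  asg <- data.frame(sequence = c("AAAAAAAA", "CCCCCCCC", "DDDDDDDDD",
                                 "EEEEEEEE", "FFFFFFFFF"),
                    length = c(8L, 8L, 9L, 8L, 9L),
                    allotype = c("B08", "B08", "B08", "A03", "A03"),
                    stringsAsFactors = FALSE)
  expect_equal(fraction_at_length(asg, "B08", 8), 2 / 3)
  expect_equal(fraction_at_length(asg, "B08", 11), 0)
  expect_error(fraction_at_length(asg, "C07", 8), "no peptides")
})

test_that("a planted 8-mer fraction is recovered within binomial error", {
  p8 <- random_pssm("HLA-B*08:01", 8, seed = 51)
  p9 <- random_pssm("HLA-B*08:01", 9, seed = 52)
  set.seed(53)
  n <- 400; frac <- 0.45
  lens <- sample(c(8, 9), n, replace = TRUE, prob = c(frac, 1 - frac))
  peps <- vapply(lens, function(L) {
    neoscan:::sample_from_pssm(if (L == 8) p8 else p9)
  }, "")
  asg <- assign_allotypes(peps, list(p8, p9))
  got <- fraction_at_length(asg, "HLA-B*08:01", 8)
  expect_lt(abs(got - frac), 3 * sqrt(frac * (1 - frac) / n))
})

test_that("mutanome matching reports DAKLRGVI and rejects its wildtype and non-spanning windows", {
  wt <- nop58_like()
  proteome <- data.frame(protein_id = "NOP58L", gene = "NOP58L",
                         sequence = wt, stringsAsFactors = FALSE)
  variants <- data.frame(protein_id = "NOP58L", gene = "NOP58L",
                         residue_pos = 95L, wt_aa = "G", mt_aa = "R",
                         vaf = 0.3, tpm = 12, stringsAsFactors = FALSE)
  mutanome <- build_mutanome(proteome, variants)
  peps <- c("DAKLRGVI",                 # mutation-spanning, mutant
            "DAKLGGVI",                 # wildtype window: in reference
            substr(mutanome$sequence, 101, 109))  # mutant protein, non-spanning
  obs <- match_mutanome(peps, mutanome, proteome)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$sequence, "DAKLRGVI")
  expect_equal(obs$mut_pos_in_peptide, 5L)
  expect_equal(obs$residue_pos, 95L)
  expect_false(obs$il_ambiguous)
})

test_that("observed neoantigens differ from the reference window only at the mutated position", {
  set.seed(61)
  cfg <- generator_config(seed = 61)
  ref <- generate_reference(cfg)
  vars <- generate_variants(cfg, ref)
  mutanome <- build_mutanome(ref$proteome, vars$missense)
  pssms <- generate_pssms(cfg)
  imm <- generate_immunopeptidome(cfg, mutanome, pssms)
  d <- dedupe_peptides(imm$records)
  obs <- match_mutanome(unlist(d$pooled, use.names = FALSE), mutanome,
                        ref$proteome)
  expect_gt(nrow(obs), 0L)
  for (r in seq_len(nrow(obs))) {
    prot <- ref$proteome$sequence[ref$proteome$protein_id ==
                                    obs$protein_id[r]]
    start <- obs$residue_pos[r] - obs$mut_pos_in_peptide[r] + 1L
    ref_window <- substr(prot, start, start + nchar(obs$sequence[r]) - 1L)
    diff <- which(strsplit(obs$sequence[r], "")[[1]] !=
                    strsplit(ref_window, "")[[1]])
    expect_equal(diff, obs$mut_pos_in_peptide[r])
  }
})

test_that("matches differing from the reference only by I/L are flagged", {
  proteome <- data.frame(protein_id = c("P1", "P2"), gene = c("g1", "g2"),
                         sequence = c("MKDAKLGGVIYQWW", "TTTTILTTTT"),
                         stringsAsFactors = FALSE)
  variants <- data.frame(protein_id = "P2", gene = "g2",
                         residue_pos = 5L, wt_aa = "I", mt_aa = "L",
                         vaf = 0.2, tpm = 3, stringsAsFactors = FALSE)
  mutanome <- build_mutanome(proteome, variants)
  # TTTTLL... is absent from the reference as exact string, but maps onto
  # TTTTIL... under I=L equivalence
  obs <- match_mutanome("TTTTLLTTTT", mutanome, proteome)
  expect_equal(nrow(obs), 1L)
  expect_true(obs$il_ambiguous)
})
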