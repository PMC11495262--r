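# Shared in-code fixtures for the test suite.

# a small caller-variant table; every field explicit
toy_calls <- function() {
  data.frame(
    chrom = c("1", "1", "2", "2", "X"),
    pos = c(100L, 100L, 50L, 50L, 9L),
    ref = c("A", "A", "C", "C", "G"),
    alt = c("T", "T", "G", "A", "T"),
    caller = c("B", "C", "A", "B", "A"),
    total_depth = c(100L, 80L, 60L, 60L, 40L),
    alt_depth = c(30L, 20L, 10L, 12L, 8L),
    stringsAsFactors = FALSE)
}

# consensus-variant rows with chosen vaf/depths (keys auto-numbered)
consensus_rows <- function(vaf, total_depth, alt_depth) {
  n <- length(vaf)
  data.frame(chrom = rep("1", n), pos = seq_len(n),
             ref = rep("A", n), alt = rep("T", n),
             source_caller = rep("m", n),
             total_depth = total_depth, alt_depth = alt_depth,
             vaf = vaf, stringsAsFactors = FALSE)
}

# a protein whose residues 91..98 read DAKLGGVI in the wildtype, as in
# the nucleolar-protein worked example (G at residue 95)
nop58_like <- function(total_len = 120L) {
  set.seed(42)
  res <- sample(aa_alphabet(), total_len, replace = TRUE)
  res[91:98] <- strsplit("DAKLGGVI", "")[[1]]
  paste(res, collapse = "")
}

# deterministic uniform PSSM (all-equal weights)
uniform_pssm <- function(allotype = "HLA-U*01:01", length = 9L) {
  w <- matrix(0, nrow = length, ncol = 20,
              dimnames = list(NULL, aa_alphabet()))
  make_pssm(allotype, w)
}

# run_config pointing at a generate_all() output directory
make_run <- function(seed, data_dir, out_dir, cfg = generator_config(seed),
                     ...) {
  run_config(
    vcfs = c(mutect2 = file.path(data_dir, "mutect2.vcf.gz"),
             varscan = file.path(data_dir, "varscan.vcf.gz"),
             strelka = file.path(data_dir, "strelka.vcf.gz")),
    proteome = file.path(data_dir, "proteome.fasta"),
    missense = file.path(data_dir, "missense.tsv"),
    peptides = file.path(data_dir, "peptides.tsv"),
    pssm_dir = file.path(data_dir, "pssms"),
    class1_allotypes = cfg$class1_allotypes,
    class2_allotypes = cfg$class2_allotypes,
    seed = seed, out_dir = out_dir, ...)
}

# brute-force enumeration of all length-L substrings covering residue_pos
brute_windows <- function(seq, residue_pos, L) {
  n <- nchar(seq)
  out <- character()
  if (L <= n) {
    for (s in 1:(n - L + 1)) {
      if (residue_pos >= s && residue_pos <= s + L - 1) {
        out <- c(out, substr(seq, s, s + L - 1))
      }
    }
  }
  out
}
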