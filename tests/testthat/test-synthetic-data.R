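test_that("the full generator is byte-identical under one seed", {
  cfg <- generator_config(seed = 81)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_all(cfg, d1)
  generate_all(cfg, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_equal(files, sort(list.files(d2, recursive = TRUE)))
  md5 <- function(dir) unname(tools::md5sum(file.path(dir, files)))
  expect_equal(md5(d1), md5(d2))
})

test_that("designed pass/fail variants survive the filters exactly as constructed", {
  cfg <- generator_config(seed = 82)
  ref <- generate_reference(cfg)
  vars <- generate_variants(cfg, ref)
  cons <- merge_caller_calls(
    vars$calls, priority = c("mutect2", "varscan", "strelka"))
  filt <- apply_hard_filters(cons)
  expect_equal(nrow(filt), vars$truth$n_pass)
  got <- sort(paste(filt$chrom, filt$pos, filt$ref, filt$alt, sep = ":"))
  expect_equal(got, vars$truth$pass_keys)
  # the designed failures sit exactly on the boundaries
  status <- filter_status(cons)
  fails <- merge(vars$variants[!is.na(vars$variants$fail_design), ],
                 status, by = c("chrom", "pos"))
  expect_true(all(!fails$pass))
  expect_true(all(fails$vaf.y[fails$fail_design == "vaf"] == 0.05))
  expect_true(all(fails$total_depth.y[fails$fail_design == "depth"] == 20))
  expect_true(all(fails$alt_depth.y[fails$fail_design == "alt"] == 5))
})

test_that("full caller overlap yields three identical VCFs", {
  cfg <- generator_config(seed = 83, caller_overlap = 1)
  ref <- generate_reference(cfg)
  d <- withr::local_tempdir()
  generate_variants(cfg, ref, out_dir = d)
  md5 <- tools::md5sum(file.path(d, c("mutect2.vcf.gz", "varscan.vcf.gz",
                                      "strelka.vcf.gz")))
  expect_equal(unname(md5[1]), unname(md5[2]))
  expect_equal(unname(md5[1]), unname(md5[3]))
})

test_that("generated class I peptides have the configured length mode", {
  cfg <- generator_config(seed = 84)
  ref <- generate_reference(cfg)
  vars <- generate_variants(cfg, ref)
  mutanome <- build_mutanome(ref$proteome, vars$missense)
  pssms <- generate_pssms(cfg)
  imm <- generate_immunopeptidome(cfg, mutanome, pssms)
  d <- dedupe_peptides(imm$records)
  h1 <- length_distribution(d$pooled[["I"]])
  expect_equal(h1$length[which.max(h1$count)], 9L)
  h2 <- length_distribution(d$pooled[["II"]])
  expect_equal(h2$length[which.max(h2$count)], 15L)
})

test_that("spiked neoantigens are recovered exactly; none without spiking", {
  cfg <- generator_config(seed = 85)
  ref <- generate_reference(cfg)
  vars <- generate_variants(cfg, ref)
  mutanome <- build_mutanome(ref$proteome, vars$missense)
  pssms <- generate_pssms(cfg)
  imm <- generate_immunopeptidome(cfg, mutanome, pssms)
  d <- dedupe_peptides(imm$records)
  obs <- match_mutanome(unlist(d$pooled, use.names = FALSE), mutanome,
                        ref$proteome)
  expect_equal(sort(unique(obs$sequence)),
               sort(unique(imm$truth$spike$sequence)))
  # no wildtype decoy is ever reported
  expect_length(intersect(obs$sequence, imm$truth$decoys), 0L)
  # zero spike-ins -> empty observed set
  cfg0 <- generator_config(seed = 85, n_spike = 0)
  imm0 <- generate_immunopeptidome(cfg0, mutanome, pssms)
  d0 <- dedupe_peptides(imm0$records)
  obs0 <- match_mutanome(unlist(d0$pooled, use.names = FALSE), mutanome,
                         ref$proteome)
  expect_equal(nrow(obs0), 0L)
})

test_that("pure-signature catalogs refit to their generating weights", {
  cfg <- generator_config(seed = 86, n_signatures = 2, n_sbs_samples = 2)
  sim <- generate_sbs_catalog(cfg)
  # construct a deterministic pure catalog from signature 1
  pure <- as.numeric(stats::rmultinom(1, 5000, sim$reference[, 1]))
  fit <- refit_exposures(pure, sim$reference)
  expect_lt(abs(fit["SYNSIG1"] - 1), 0.02)
  # zero mutations give a zero catalog
  cfg0 <- generator_config(seed = 86, n_snvs_per_sample = 0)
  sim0 <- generate_sbs_catalog(cfg0)
  expect_true(all(sim0$catalogs == 0))
  # same seed, same catalogs
  sim2 <- generate_sbs_catalog(generator_config(seed = 86,
                                                n_signatures = 2,
                                                n_sbs_samples = 2))
  expect_equal(sim$catalogs, sim2$catalogs)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(generator_config(n_variants = 5, n_fail_vaf = 10),
               "exceed")
  expect_error(generator_config(class1_length_probs = c("9" = 0.5)),
               "sum to 1")
})
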