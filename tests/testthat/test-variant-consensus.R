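test_that("merge keeps one record per variant from the highest-priority caller", {
  calls <- toy_calls()
  out <- merge_caller_calls(calls, priority = c("A", "B", "C"))
  # 1:100 A>T reported by B and C -> B wins under priority A,B,C
  row <- out[out$chrom == "1" & out$pos == 100, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$source_caller, "B")
  expect_equal(row$vaf, 30 / 100)
  # 2:50 C>G and C>A are distinct variants (different alt)
  expect_equal(sum(out$chrom == "2" & out$pos == 50), 2L)
  # output size = number of distinct keys
  keys <- unique(paste(calls$chrom, calls$pos, calls$ref, calls$alt))
  expect_equal(nrow(out), length(keys))
})

test_that("merge errors on a caller missing from the priority order", {
  expect_error(merge_caller_calls(toy_calls(), priority = c("A", "B")),
               "C")
})

test_that("merge is invariant to input order and counts distinct keys (random tables)", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    calls <- data.frame(
      chrom = as.character(sample(1:3, n, replace = TRUE)),
      pos = sample(1:10, n, replace = TRUE),
      ref = sample(c("A", "C"), n, replace = TRUE),
      alt = sample(c("G", "T"), n, replace = TRUE),
      caller = sample(c("m", "v", "s"), n, replace = TRUE),
      total_depth = sample(20:200, n, replace = TRUE),
      stringsAsFactors = FALSE)
    calls$alt_depth <- pmin(calls$total_depth, sample(1:50, n, TRUE))
    # a caller reports a given variant at most once
    calls <- calls[!duplicated(calls[, c("chrom", "pos", "ref", "alt",
                                         "caller")]), , drop = FALSE]
    n <- nrow(calls)
    out1 <- merge_caller_calls(calls, c("m", "v", "s"))
    # brute-force key-grouping oracle for the output size
    expect_equal(nrow(out1),
                 length(unique(paste(calls$chrom, calls$pos, calls$ref,
                                     calls$alt))))
    perm <- calls[sample.int(n), , drop = FALSE]
    out2 <- merge_caller_calls(perm, c("m", "v", "s"))
    expect_equal(out1, out2)
  }
})

test_that("VAF is alt/total with a zero-depth guard and validation", {
  expect_equal(compute_vaf(5, 100), 0.05)
  expect_equal(compute_vaf(0, 50), 0)
  expect_equal(compute_vaf(67, 100), 0.67)
  expect_equal(compute_vaf(0, 0), 0)
  expect_error(compute_vaf(10, 5), "exceed")
})

test_that("hard filters are strict at every boundary", {
  v <- consensus_rows(vaf = c(0.05, 0.10),
                      total_depth = c(30L, 21L),
                      alt_depth = c(6L, 6L))
  out <- apply_hard_filters(v)
  # VAF exactly 0.05 is removed; all-strict passer kept
  expect_equal(out$pos, 2L)
})

test_that("each single-criterion failure is caught; one clean passer survives", {
  # six variants: two fail VAF only, one depth only, one alt only,
  # one fails everything, one passes
  v <- consensus_rows(
    vaf = c(0.05, 0.04, 0.40, 0.10, 0.02, 0.30),
    total_depth = c(200L, 200L, 20L, 60L, 20L, 100L),
    alt_depth = c(10L, 8L, 8L, 5L, 2L, 30L))
  status <- filter_status(v)
  expect_equal(sum(status$pass), 1L)
  expect_equal(which(status$pass), 6L)
  expect_equal(status$fail_reason[1], "vaf")
  expect_equal(status$fail_reason[3], "total_depth")
  expect_equal(status$fail_reason[4], "alt_depth")
  expect_equal(status$fail_reason[5], "vaf;total_depth;alt_depth")
  # brute-force predicate oracle
  oracle <- v$vaf > 0.05 & v$total_depth > 20 & v$alt_depth > 5
  expect_equal(status$pass, oracle)
})

test_that("filtering is idempotent and monotone in the thresholds", {
  set.seed(11)
  dp <- sample(5:60, 50, replace = TRUE)
  ad <- pmin(dp, sample(0:20, 50, replace = TRUE))
  v <- consensus_rows(vaf = compute_vaf(ad, dp), total_depth = dp,
                      alt_depth = ad)
  once <- apply_hard_filters(v)
  expect_equal(apply_hard_filters(once), once)
  base_n <- nrow(once)
  for (th in list(filter_thresholds(min_vaf = 0.1),
                  filter_thresholds(min_total_depth = 30),
                  filter_thresholds(min_alt_depth = 8))) {
    expect_lte(nrow(apply_hard_filters(v, th)), base_n)
  }
})

test_that("mutational burden divides mutations by exome megabases", {
  expect_equal(mutational_burden(3720, 30), 124)
  expect_equal(mutational_burden(1200, 30), 40)
  expect_equal(mutational_burden(0, 30), 0)
  expect_error(mutational_burden(10, 0), "positive")
})

test_that("caller VCFs round-trip through write and read", {
  calls <- toy_calls()[toy_calls()$caller == "B", ]
  path <- withr::local_tempfile(fileext = ".vcf.gz")
  neoscan:::write_caller_vcf(calls, path)
  back <- read_caller_vcf(path, caller = "B")
  ord <- genome_order(calls)
  expect_equal(back$chrom, calls$chrom[ord])
  expect_equal(back$pos, calls$pos[ord])
  expect_equal(back$total_depth, calls$total_depth[ord])
  expect_equal(back$alt_depth, calls$alt_depth[ord])
})

test_that("multi-allelic VCF records are rejected with a clear message", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tT",
               "1\t10\t.\tA\tC,G\t.\tPASS\t.\tDP:AD\t50:30,10,10"),
             path)
  expect_error(read_caller_vcf(path, "m"), "multi-allelic")
})
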