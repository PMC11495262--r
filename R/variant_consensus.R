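# Multi-caller somatic variant consensus: priority merging, hard filters,
# mutational burden. Variants travel as plain data frames with one row per
# call and columns chrom, pos, ref, alt, caller, total_depth, alt_depth.

DNA_BASES <- c("A", "C", "G", "T")

validate_caller_variants <- function(calls) {
  need <- c("chrom", "pos", "ref", "alt", "caller", "total_depth", "alt_depth")
  missing <- setdiff(need, names(calls))
  if (length(missing) > 0L) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(calls) == 0L) return(invisible(calls))
  if (any(calls$pos < 1L)) stop("positions must be 1-based (>= 1)")
  if (any(calls$alt_depth > calls$total_depth)) {
    stop("alt_depth exceeds total_depth for some calls")
  }
  if (any(calls$alt_depth < 0L) || any(calls$total_depth < 0L)) {
    stop("read depths must be non-negative")
  }
  ok_allele <- function(a) grepl("^[ACGT]+$", a)
  if (!all(ok_allele(calls$ref)) || !all(ok_allele(calls$alt))) {
    stop("alleles must be non-empty strings over {A,C,G,T}; ",
         "multi-allelic records must be split upstream")
  }
  if (any(calls$ref == calls$alt)) stop("ref and alt alleles must differ")
  invisible(calls)
}

#' Compute variant allele fraction from read depths
#'
#' @param alt_depth Integer vector of variant-supporting read counts.
#' @param total_depth Integer vector of total read counts at the site.
#' @return Numeric VAF in \[0, 1\]; 0 where `total_depth` is 0.
#' @export
#' @examples
#' compute_vaf(5, 100)   # 0.05
#' compute_vaf(67, 100)  # 0.67
compute_vaf <- function(alt_depth, total_depth) {
  if (any(alt_depth < 0) || any(total_depth < 0)) {
    stop("read depths must be non-negative")
  }
  if (any(alt_depth > total_depth)) {
    stop("alt_depth cannot exceed total_depth")
  }
  ifelse(total_depth > 0, alt_depth / total_depth, 0)
}

#' Merge somatic calls from multiple callers under a priority order
#'
#' For each distinct variant key (chrom, pos, ref, alt) exactly one record
#' is kept: the one from the highest-priority caller that reported it.
#' Records at the same site with different alternate alleles are distinct
#' variants. VAF is recomputed from the allele depths of the kept record so
#' the downstream filter is caller-agnostic.
#'
#' @param calls Data frame of caller variants (columns `chrom`, `pos`,
#'   `ref`, `alt`, `caller`, `total_depth`, `alt_depth`).
#' @param priority Character vector of caller identifiers, highest priority
#'   first, e.g. `c("mutect2", "varscan", "strelka")`.
#' @return Consensus data frame sorted by (chrom, pos, ref, alt) with one
#'   row per variant and columns `chrom`, `pos`, `ref`, `alt`,
#'   `source_caller`, `total_depth`, `alt_depth`, `vaf`.
#' @export
merge_caller_calls <- function(calls, priority) {
  validate_caller_variants(calls)
  unknown <- setdiff(unique(calls$caller), priority)
  if (length(unknown) > 0L) {
    stop("caller(s) not in priority order: ", paste(unknown, collapse = ", "))
  }
  if (nrow(calls) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      source_caller = character(), total_depth = integer(),
                      alt_depth = integer(), vaf = numeric()))
  }
  calls$.prio <- match(calls$caller, priority)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  # within each key keep the best-priority record (stable on input order)
  keep <- unlist(lapply(split(seq_len(nrow(calls)), key), function(idx) {
    idx[which.min(calls$.prio[idx])]
  }), use.names = FALSE)
  out <- calls[keep, , drop = FALSE]
  out <- data.frame(chrom = out$chrom, pos = out$pos, ref = out$ref,
                    alt = out$alt, source_caller = out$caller,
                    total_depth = out$total_depth, alt_depth = out$alt_depth,
                    vaf = compute_vaf(out$alt_depth, out$total_depth),
                    stringsAsFactors = FALSE)
  out <- out[genome_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hard-filter thresholds for consensus variants
#'
#' All three comparisons are strictly greater-than, so boundary values
#' (VAF exactly `min_vaf`, depth exactly `min_total_depth`, variant reads
#' exactly `min_alt_depth`) are excluded.
#'
#' @param min_vaf Minimum variant allele fraction, exclusive (default 0.05).
#' @param min_total_depth Minimum total coverage, exclusive (default 20).
#' @param min_alt_depth Minimum variant-supporting reads, exclusive
#'   (default 5).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_vaf = 0.05, min_total_depth = 20,
                              min_alt_depth = 5) {
  if (min_vaf < 0 || min_total_depth < 0 || min_alt_depth < 0) {
    stop("thresholds must be non-negative")
  }
  structure(list(min_vaf = min_vaf, min_total_depth = min_total_depth,
                 min_alt_depth = min_alt_depth),
            class = "filter_thresholds")
}

#' Per-variant filter status
#'
#' @param variants Consensus variant data frame (needs `vaf`,
#'   `total_depth`, `alt_depth`).
#' @param thresholds A [filter_thresholds()] object.
#' @return The input with logical `pass` and character `fail_reason`
#'   columns (`NA` where passing; semicolon-joined criteria otherwise).
#' @export
filter_status <- function(variants, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  n <- nrow(variants)
  reasons <- character(n)
  fails <- cbind(
    vaf = !(variants$vaf > thresholds$min_vaf),
    total_depth = !(variants$total_depth > thresholds$min_total_depth),
    alt_depth = !(variants$alt_depth > thresholds$min_alt_depth)
  )
  for (i in seq_len(n)) {
    f <- colnames(fails)[fails[i, ]]
    reasons[i] <- if (length(f) == 0L) NA_character_ else
      paste(f, collapse = ";")
  }
  variants$pass <- !apply(fails, 1L, any)
  variants$fail_reason <- reasons
  variants
}

#' Apply the hard filters to consensus variants
#'
#' Keeps exactly those variants with `vaf > min_vaf` AND
#' `total_depth > min_total_depth` AND `alt_depth > min_alt_depth`
#' (all strict). Input order is preserved.
#'
#' @inheritParams filter_status
#' @return The surviving subset of `variants`.
#' @export
apply_hard_filters <- function(variants, thresholds = filter_thresholds()) {
  status <- filter_status(variants, thresholds)
  out <- variants[status$pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutational burden in mutations per megabase
#'
#' @param n_coding_mutations Number of somatic coding mutations.
#' @param exome_size_mb Exome size in megabases (default 30).
#' @return Mutations per Mb.
#' @export
#' @examples
#' mutational_burden(3720, 30)  # 124
mutational_burden <- function(n_coding_mutations, exome_size_mb = 30) {
  if (any(exome_size_mb <= 0)) stop("exome size must be positive")
  if (any(n_coding_mutations < 0)) stop("mutation count must be non-negative")
  n_coding_mutations / exome_size_mb
}

#' Read one caller's somatic VCF into a variant table
#'
#' Extracts CHROM/POS/REF/ALT plus per-sample AD and DP FORMAT fields for
#' the tumour sample. Multi-allelic ALT fields are rejected: splitting and
#' left-alignment are assumed done upstream.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @param caller Caller identifier to stamp on every record.
#' @param sample Tumour sample name; default the first sample column.
#' @return Caller-variant data frame (see [merge_caller_calls()]).
#' @export
read_caller_vcf <- function(path, caller, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multi-allelic ALT records in ", path,
         "; split and left-align variants upstream")
  }
  samples <- colnames(vcf@gt)[-1]
  if (is.null(sample)) sample <- samples[1]
  if (!sample %in% samples) {
    stop("sample '", sample, "' not present in ", path)
  }
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[, sample]
  ad <- vcfR::extract.gt(vcf, element = "AD")[, sample]
  # AD is "ref,alt" for bi-allelic records
  alt_depth <- as.integer(vapply(strsplit(ad, ",", fixed = TRUE),
                                 function(x) x[2], ""))
  out <- data.frame(chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = fix[, "REF"], alt = alt,
                    caller = caller,
                    total_depth = as.integer(dp),
                    alt_depth = alt_depth,
                    stringsAsFactors = FALSE)
  validate_caller_variants(out)
  out
}

#' Write consensus variants as VCF and tab-separated summary
#'
#' The VCF carries an `SRC` INFO tag recording the source caller; the
#' summary records depth, VAF and pass/fail with the failing criterion.
#'
#' @param consensus Consensus variant data frame from
#'   [merge_caller_calls()].
#' @param vcf_path Output VCF path (written gzipped, so use `.vcf.gz`).
#' @param summary_path Output TSV path.
#' @param thresholds Thresholds used for the summary's pass/fail column.
#' @param sample Sample name for the (depth-only) genotype column.
#' @return Invisibly, the summary data frame.
#' @export
write_consensus <- function(consensus, vcf_path, summary_path,
                            thresholds = filter_thresholds(),
                            sample = "TUMOUR") {
  status <- filter_status(consensus, thresholds)
  summary <- data.frame(chrom = consensus$chrom, pos = consensus$pos,
                        ref = consensus$ref, alt = consensus$alt,
                        caller = consensus$source_caller,
                        depth = consensus$total_depth,
                        alt_depth = consensus$alt_depth,
                        vaf = consensus$vaf,
                        pass = status$pass,
                        fail_reason = status$fail_reason,
                        stringsAsFactors = FALSE)
  utils::write.table(summary, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Source caller\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  n <- nrow(consensus)
  fix <- matrix(c(consensus$chrom, as.character(consensus$pos),
                  rep(".", n), consensus$ref, consensus$alt,
                  rep(".", n), rep(".", n),
                  paste0("SRC=", consensus$source_caller)),
                ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gt <- matrix(c(rep("DP:AD", n),
                 paste0(consensus$total_depth, ":",
                        consensus$total_depth - consensus$alt_depth, ",",
                        consensus$alt_depth)),
               ncol = 2, dimnames = list(NULL, c("FORMAT", sample)))
  vcf <- new_vcfR(meta, fix, gt)
  vcfR::write.vcf(vcf, file = vcf_path)
  invisible(summary)
}
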