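# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with known ground truth: a reference proteome with
# expression, somatic calls from three pseudo-callers with designed
# filter failures, allotype PSSMs, an immunopeptidome with spiked
# mutation-spanning peptides and near-miss decoys, and SBS96 catalogs
# drawn from known signature mixtures. One global seed fans out to
# independent per-generator streams (see derive_stream_seed), so the
# same seed always reproduces byte-identical outputs.

#' Generator configuration
#'
#' Defaults emulate the study conditions at desk scale: ~100x exome
#' coverage, somatic VAFs mostly between 0.05 and 0.5, a donor typed for
#' three class I allotypes and one DRB1 allotype, class I peptides with
#' a 9-mer length mode and class II with a 15-mer mode, and per-sample
#' mutation spectra drawn from a small number of signatures.
#'
#' @param seed Global integer seed.
#' @param n_proteins Reference proteome size.
#' @param protein_length Min/max protein length (residues).
#' @param n_variants Somatic coding variants planted for the donor.
#' @param n_fail_vaf,n_fail_depth,n_fail_alt Variants designed to fail
#'   exactly one hard filter each (at the boundary value, which the
#'   strict comparisons must exclude).
#' @param mean_depth Mean sequencing depth at variant sites.
#' @param vaf_shape1,vaf_shape2 Beta parameters of the tumour VAF
#'   distribution (defaults give a median near 0.2).
#' @param caller_overlap Probability each pseudo-caller independently
#'   reports a variant (every variant is reported by at least one).
#' @param class1_allotypes,class2_allotypes Donor HLA typing.
#' @param motif_strength,n_anchors Anchor weight and count of the
#'   generated PSSMs.
#' @param n_eluted_class1,n_eluted_class2 Eluted peptides per class.
#' @param class1_length_probs Named probabilities of class I lengths.
#' @param class2_length_probs Named probabilities of class II lengths.
#' @param duplicate_fraction Fraction of peptide records re-emitted as
#'   duplicates (exercises deduplication).
#' @param fail_fdr_fraction Fraction of records drawn above the 1% FDR
#'   cutoff.
#' @param n_spike Planted mutation-spanning neoantigen peptides.
#' @param n_signatures,n_sbs_samples,n_snvs_per_sample Signature-mixture
#'   simulation: number of synthetic reference signatures, samples, and
#'   SNVs per sample.
#' @param exposure_alpha Dirichlet concentration of per-sample signature
#'   exposures. The default 0.3 gives samples dominated by one or two
#'   mutational processes, as real cohorts are; dense mixtures
#'   (large alpha) make de novo extraction under-determined.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             n_proteins = 150,
                             protein_length = c(120, 600),
                             n_variants = 40,
                             n_fail_vaf = 4, n_fail_depth = 4,
                             n_fail_alt = 4,
                             mean_depth = 100,
                             vaf_shape1 = 2, vaf_shape2 = 8,
                             caller_overlap = 0.8,
                             class1_allotypes = c("HLA-A*03:01",
                                                  "HLA-B*07:02",
                                                  "HLA-B*08:01"),
                             class2_allotypes = "DRB1*03:01",
                             motif_strength = 3, n_anchors = 2,
                             n_eluted_class1 = 1500,
                             n_eluted_class2 = 500,
                             class1_length_probs = c("8" = 0.20,
                                                     "9" = 0.45,
                                                     "10" = 0.20,
                                                     "11" = 0.15),
                             class2_length_probs = c("13" = 0.15,
                                                     "14" = 0.20,
                                                     "15" = 0.35,
                                                     "16" = 0.20,
                                                     "17" = 0.10),
                             duplicate_fraction = 0.05,
                             fail_fdr_fraction = 0.10,
                             n_spike = 3,
                             n_signatures = 4,
                             n_sbs_samples = 7,
                             n_snvs_per_sample = 10000,
                             exposure_alpha = 0.3) {
  n_fail <- n_fail_vaf + n_fail_depth + n_fail_alt
  if (n_fail > n_variants) {
    stop("designed failures exceed n_variants")
  }
  if (abs(sum(class1_length_probs) - 1) > 1e-8 ||
      abs(sum(class2_length_probs) - 1) > 1e-8) {
    stop("length probabilities must sum to 1")
  }
  cfg <- as.list(environment())
  cfg$n_fail <- n_fail
  structure(cfg, class = "generator_config")
}

#' Generate a reference proteome with expression
#'
#' Random proteins over the 20-letter alphabet with log-normal TPM
#' (meanlog 2, sdlog 1.5 — a heavy-tailed expression distribution with
#' most genes in the 1-100 TPM range).
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; writes `proteome.fasta` and
#'   `expression.tsv` when given.
#' @return List with `proteome` (data frame) and `expression`
#'   (gene/tpm data frame).
#' @export
generate_reference <- function(config, out_dir = NULL) {
  set.seed(derive_stream_seed(config$seed, "reference"))
  n <- config$n_proteins
  lens <- sample(config$protein_length[1]:config$protein_length[2], n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
  }, "")
  ids <- sprintf("PROT%04d", seq_len(n))
  genes <- sprintf("GENE%04d", seq_len(n))
  proteome <- data.frame(protein_id = ids, gene = genes, sequence = seqs,
                         stringsAsFactors = FALSE)
  tpm <- round(stats::rlnorm(n, meanlog = 2, sdlog = 1.5), 2)
  expression <- data.frame(gene = genes, tpm = tpm,
                           stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_proteome_fasta(proteome, file.path(out_dir, "proteome.fasta"))
    utils::write.table(expression, file.path(out_dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(proteome = proteome, expression = expression)
}

# depths/VAF for one designed filter failure; each hits exactly one
# boundary the strict filters must exclude
designed_failure <- function(kind) {
  switch(kind,
         vaf = list(total_depth = 200L, alt_depth = 10L),    # VAF = 0.05
         depth = list(total_depth = 20L, alt_depth = 8L),    # DP = 20
         alt = list(total_depth = 50L, alt_depth = 5L))      # AD = 5
}

#' Generate somatic variant calls from three pseudo-callers
#'
#' Plants `n_variants` coding SNVs on distinct proteins. A configured
#' number are designed to fail exactly one hard filter each, at the
#' boundary value; the remainder are guaranteed to pass all three
#' filters. Calls are distributed across the pseudo-callers mutect2,
#' varscan and strelka with the configured overlap, and each caller's
#' calls are written as a VCF with AD/DP FORMAT fields. The missense
#' table covers the passing variants only (mirroring a
#' filtered-then-annotated flow).
#'
#' @param config A [generator_config()].
#' @param reference Output of [generate_reference()].
#' @param out_dir Optional directory; writes `<caller>.vcf.gz`,
#'   `missense.tsv` and `snv_contexts.tsv` when given.
#' @return List with `calls` (all caller records), `variants` (one row
#'   per planted variant with genomic and protein coordinates, depths,
#'   designed `fail_design`), `missense` (table for passing variants),
#'   `contexts` (chrom/pos/trinucleotide), `truth` (passing keys and
#'   counts).
#' @export
generate_variants <- function(config, reference, out_dir = NULL) {
  set.seed(derive_stream_seed(config$seed, "variants"))
  proteome <- reference$proteome
  n <- config$n_variants
  if (n > nrow(proteome)) stop("more variants than proteins")
  prot_idx <- sample.int(nrow(proteome), n)
  residue_pos <- vapply(prot_idx, function(i) {
    sample.int(nchar(proteome$sequence[i]), 1L)
  }, integer(1))
  wt_aa <- substr(proteome$sequence[prot_idx], residue_pos, residue_pos)
  mt_aa <- vapply(wt_aa, function(a) {
    sample(setdiff(aa_alphabet(), a), 1L)
  }, "", USE.NAMES = FALSE)

  chrom <- as.character(sample(1:22, n, replace = TRUE))
  pos <- sample.int(5e7L, n)  # distinct genomic positions
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "",
                USE.NAMES = FALSE)
  context <- vapply(ref, function(b) {
    paste0(sample(bases, 1L), b, sample(bases, 1L))
  }, "", USE.NAMES = FALSE)

  fail_design <- rep(NA_character_, n)
  fail_design[seq_len(config$n_fail_vaf)] <- "vaf"
  fail_design[config$n_fail_vaf + seq_len(config$n_fail_depth)] <- "depth"
  fail_design[config$n_fail_vaf + config$n_fail_depth +
                seq_len(config$n_fail_alt)] <- "alt"
  fail_design <- sample(fail_design)  # shuffle designed failures

  total_depth <- integer(n)
  alt_depth <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(fail_design[i])) {
      d <- designed_failure(fail_design[i])
      total_depth[i] <- d$total_depth
      alt_depth[i] <- d$alt_depth
    } else {
      dp <- max(30L, stats::rpois(1, config$mean_depth))
      vaf <- stats::rbeta(1, config$vaf_shape1, config$vaf_shape2)
      ad <- round(vaf * dp)
      ad <- max(ad, 6L)                        # AD > 5
      if (ad / dp <= 0.05) ad <- ceiling(0.05 * dp) + 1L  # VAF > 0.05
      total_depth[i] <- dp
      alt_depth[i] <- min(ad, dp)
    }
  }
  vaf <- compute_vaf(alt_depth, total_depth)

  callers <- c("mutect2", "varscan", "strelka")
  reported <- matrix(stats::runif(n * 3) < config$caller_overlap, n, 3,
                     dimnames = list(NULL, callers))
  none <- which(rowSums(reported) == 0L)
  for (i in none) reported[i, sample.int(3L, 1L)] <- TRUE

  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         total_depth = total_depth, alt_depth = alt_depth,
                         vaf = vaf,
                         protein_id = proteome$protein_id[prot_idx],
                         gene = proteome$gene[prot_idx],
                         residue_pos = residue_pos,
                         wt_aa = wt_aa, mt_aa = mt_aa,
                         fail_design = fail_design,
                         stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(callers, function(cl) {
    sub <- variants[reported[, cl], c("chrom", "pos", "ref", "alt",
                                      "total_depth", "alt_depth")]
    if (nrow(sub) == 0L) return(NULL)
    sub$caller <- cl
    sub
  }))
  rownames(calls) <- NULL

  tpm <- reference$expression$tpm[match(variants$gene,
                                        reference$expression$gene)]
  pass <- is.na(variants$fail_design)
  missense <- data.frame(protein_id = variants$protein_id[pass],
                         gene = variants$gene[pass],
                         residue_pos = variants$residue_pos[pass],
                         wt_aa = variants$wt_aa[pass],
                         mt_aa = variants$mt_aa[pass],
                         vaf = variants$vaf[pass],
                         tpm = tpm[pass], stringsAsFactors = FALSE)
  contexts <- data.frame(chrom = chrom, pos = pos,
                         trinucleotide = context,
                         stringsAsFactors = FALSE)
  truth <- list(
    n_variants = n, n_pass = sum(pass),
    pass_keys = sort(paste(variants$chrom[pass], variants$pos[pass],
                           variants$ref[pass], variants$alt[pass],
                           sep = ":")),
    n_fail_vaf = config$n_fail_vaf, n_fail_depth = config$n_fail_depth,
    n_fail_alt = config$n_fail_alt)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cl in callers) {
      sub <- calls[calls$caller == cl, , drop = FALSE]
      write_caller_vcf(sub, file.path(out_dir, paste0(cl, ".vcf.gz")))
    }
    utils::write.table(missense, file.path(out_dir, "missense.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(contexts, file.path(out_dir, "snv_contexts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(calls = calls, variants = variants, missense = missense,
       contexts = contexts, truth = truth)
}

# write one caller's calls as a minimal VCFv4.2 with AD/DP (gzipped)
write_caller_vcf <- function(calls, path, sample = "TUMOUR") {
  ord <- genome_order(calls)
  calls <- calls[ord, , drop = FALSE]
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
            "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  n <- nrow(calls)
  fix <- matrix(c(calls$chrom, as.character(calls$pos), rep(".", n),
                  calls$ref, calls$alt, rep(".", n), rep("PASS", n),
                  rep(".", n)),
                ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gt <- matrix(c(rep("DP:AD", n),
                 paste0(calls$total_depth, ":",
                        calls$total_depth - calls$alt_depth, ",",
                        calls$alt_depth)),
               ncol = 2, dimnames = list(NULL, c("FORMAT", sample)))
  vcf <- new_vcfR(meta, fix, gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}

#' Generate donor allotype PSSMs
#'
#' One anchor-style PSSM per class I allotype at each class I length
#' (8-11) and per DRB1 allotype at the class II length (15). Each
#' matrix's seed derives from the global seed and its (allotype, length),
#' so PSSMs are stable as generators are added.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory for [write_pssm_set()].
#' @return List of `pssm` objects.
#' @export
generate_pssms <- function(config, out_dir = NULL) {
  combos <- rbind(
    expand.grid(allotype = config$class1_allotypes, length = 8:11,
                stringsAsFactors = FALSE),
    expand.grid(allotype = config$class2_allotypes, length = 15L,
                stringsAsFactors = FALSE))
  pssms <- lapply(seq_len(nrow(combos)), function(i) {
    random_pssm(combos$allotype[i], combos$length[i],
                n_anchors = config$n_anchors,
                strength = config$motif_strength,
                seed = derive_stream_seed(
                  config$seed,
                  paste0("pssm|", combos$allotype[i], "|",
                         combos$length[i])))
  })
  if (!is.null(out_dir)) write_pssm_set(pssms, out_dir)
  pssms
}

# sample one peptide from a PSSM: residue probabilities per position
# proportional to exp(weight)
sample_from_pssm <- function(pssm) {
  aa <- aa_alphabet()
  paste(vapply(seq_len(pssm$length), function(i) {
    p <- exp(pssm$weights[i, ])
    sample(aa, 1L, prob = p / sum(p))
  }, ""), collapse = "")
}

#' Generate a synthetic immunopeptidome with spiked neoantigens
#'
#' Background class I peptides are sampled from the donor's class I
#' PSSMs with the configured length distribution (mode 9); class II
#' peptides from the DRB1 PSSM at length 15, with other class II lengths
#' drawn as unstructured background. Planted neoantigens are legal
#' mutation-spanning windows of mutanome entries (consistent with the
#' mutanome by construction); near-miss decoys — the corresponding
#' wildtype windows and non-spanning windows of the mutated protein —
#' are added, and a configured fraction of records is drawn above the
#' FDR cutoff or duplicated.
#'
#' @param config A [generator_config()].
#' @param mutanome Data frame from [build_mutanome()] (needs at least
#'   `n_spike` entries with room for an interior class I window).
#' @param pssms Donor PSSMs from [generate_pssms()].
#' @param sample_id Donor identifier stamped on every record.
#' @param out_dir Optional directory; writes `peptides.tsv`.
#' @return List with `records` (the eluted-peptide table) and `truth`
#'   (spiked sequences with their mutanome coordinates, and decoy
#'   sequences).
#' @export
generate_immunopeptidome <- function(config, mutanome, pssms,
                                     sample_id = "EN-sim-01",
                                     out_dir = NULL) {
  set.seed(derive_stream_seed(config$seed, "immunopeptidome"))
  key <- function(p) paste0(p$allotype, "|", p$length)
  by_key <- stats::setNames(pssms, vapply(pssms, key, ""))

  draw_class <- function(n_records, allotypes, length_probs) {
    lens <- as.integer(sample(names(length_probs), n_records,
                              replace = TRUE, prob = length_probs))
    vapply(lens, function(L) {
      allo <- sample(allotypes, 1L)
      p <- by_key[[paste0(allo, "|", L)]]
      if (is.null(p)) {
        paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
      } else {
        sample_from_pssm(p)
      }
    }, "")
  }
  seqs1 <- draw_class(config$n_eluted_class1, config$class1_allotypes,
                      config$class1_length_probs)
  seqs2 <- draw_class(config$n_eluted_class2, config$class2_allotypes,
                      config$class2_length_probs)

  # planted neoantigens: pick a variant, then one of its legal windows
  spike <- list()
  if (config$n_spike > 0L) {
    if (nrow(mutanome) < config$n_spike) {
      stop("not enough mutanome entries for the requested spike-ins")
    }
    picks <- sample.int(nrow(mutanome), config$n_spike)
    for (j in picks) {
      w <- enumerate_mutation_windows(mutanome$sequence[j],
                                      mutanome$wildtype_sequence[j],
                                      mutanome$residue_pos[j],
                                      lengths = 8:11,
                                      protein_id = mutanome$protein_id[j])
      if (nrow(w) == 0L) {
        stop("mutanome entry ", mutanome$mutanome_id[j],
             " admits no class I window; cannot spike it in")
      }
      # an eluted peptide is by definition HLA-bound, so plant the
      # best-binding window across the donor's class I allotypes
      best_nM <- vapply(seq_len(nrow(w)), function(r) {
        min(vapply(config$class1_allotypes, function(allo) {
          p <- by_key[[paste0(allo, "|", w$length[r])]]
          if (is.null(p)) Inf else predict_affinity(w$sequence[r], p)
        }, numeric(1)))
      }, numeric(1))
      w <- w[which.min(best_nM), , drop = FALSE]
      spike[[length(spike) + 1L]] <- data.frame(
        sequence = w$sequence, wildtype_sequence = w$wildtype_sequence,
        mutanome_id = mutanome$mutanome_id[j],
        protein_id = mutanome$protein_id[j],
        residue_pos = mutanome$residue_pos[j],
        mut_pos_in_peptide = w$mut_pos_in_peptide,
        stringsAsFactors = FALSE)
    }
  }
  spike_df <- if (length(spike) > 0L) do.call(rbind, spike) else
    data.frame(sequence = character(), wildtype_sequence = character(),
               mutanome_id = character(), protein_id = character(),
               residue_pos = integer(), mut_pos_in_peptide = integer())

  # near-miss decoys: wildtype windows (present in the reference) and
  # non-spanning windows of the mutated proteins
  decoys <- spike_df$wildtype_sequence
  for (j in seq_len(nrow(spike_df))) {
    m <- mutanome[mutanome$mutanome_id == spike_df$mutanome_id[j], ]
    n <- nchar(m$sequence)
    L <- 9L
    away <- setdiff(seq_len(n - L + 1L),
                    (m$residue_pos - L + 1L):m$residue_pos)
    if (length(away) > 0L) {
      s <- away[sample.int(length(away), 1L)]
      decoys <- c(decoys, substr(m$sequence, s, s + L - 1L))
    }
  }

  all_seqs <- c(seqs1, spike_df$sequence, decoys)
  all_class <- c(rep("I", length(seqs1)),
                 rep("I", nrow(spike_df) + length(decoys)))
  all_seqs <- c(all_seqs, seqs2)
  all_class <- c(all_class, rep("II", length(seqs2)))

  n_rec <- length(all_seqs)
  fdr <- stats::runif(n_rec, 0, 0.01)
  n_bad <- round(config$fail_fdr_fraction * length(seqs1))
  bad <- sample(seq_along(seqs1), n_bad)  # only background records fail
  fdr[bad] <- stats::runif(n_bad, 0.011, 0.05)

  records <- data.frame(sequence = all_seqs, sample = sample_id,
                        hla_class = all_class, fdr = round(fdr, 5),
                        stringsAsFactors = FALSE)
  n_dup <- round(config$duplicate_fraction * n_rec)
  if (n_dup > 0L) {
    records <- rbind(records,
                     records[sample.int(n_rec, n_dup, replace = TRUE), ])
  }
  rownames(records) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(records, file.path(out_dir, "peptides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(records = records,
       truth = list(spike = spike_df, decoys = decoys))
}

#' Generate synthetic reference signatures
#'
#' Sparse Dirichlet draws over the 96 channels (small concentration
#' makes the signatures near-orthogonal, as distinct mutational
#' processes are), columns summing to 1.
#'
#' @param k Number of signatures.
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration (default 0.1).
#' @return 96 x k matrix with columns `SYNSIG1..k`.
#' @export
generate_reference_signatures <- function(k, seed = 1, alpha = 0.1) {
  set.seed(seed)
  sig <- matrix(stats::rgamma(96 * k, shape = alpha), nrow = 96)
  sig <- sweep(sig, 2, colSums(sig), "/")
  dimnames(sig) <- list(sbs96_channels(), paste0("SYNSIG", seq_len(k)))
  sig
}

#' Generate SBS96 catalogs from known signature mixtures
#'
#' Per-sample exposures are Dirichlet draws over the synthetic reference
#' signatures; catalogs are multinomial draws of `n_snvs_per_sample`
#' mutations from each sample's mixture spectrum. Truth exposures are
#' returned for recovery tests.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional directory; writes `sbs_catalogs.tsv`,
#'   `reference_signatures.tsv` and `true_exposures.tsv`.
#' @return List with `catalogs` (96 x n_samples counts), `reference`
#'   (96 x k signatures), `exposures` (k x n_samples true proportions).
#' @export
generate_sbs_catalog <- function(config, out_dir = NULL) {
  set.seed(derive_stream_seed(config$seed, "sbs"))
  k <- config$n_signatures
  nsamp <- config$n_sbs_samples
  reference <- generate_reference_signatures(
    k, seed = derive_stream_seed(config$seed, "sbs-reference"))
  expo <- matrix(stats::rgamma(k * nsamp, shape = config$exposure_alpha),
                 nrow = k)
  expo <- sweep(expo, 2, colSums(expo), "/")
  dimnames(expo) <- list(colnames(reference),
                         sprintf("SAMPLE%02d", seq_len(nsamp)))
  catalogs <- sapply(seq_len(nsamp), function(j) {
    p <- as.numeric(reference %*% expo[, j])
    if (config$n_snvs_per_sample == 0L) return(integer(96))
    as.integer(stats::rmultinom(1, config$n_snvs_per_sample, p))
  })
  dimnames(catalogs) <- list(sbs96_channels(), colnames(expo))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_sbs_matrix(catalogs, file.path(out_dir, "sbs_catalogs.tsv"))
    write_sbs_matrix(reference,
                     file.path(out_dir, "reference_signatures.tsv"))
    utils::write.table(data.frame(signature = rownames(expo), expo,
                                  check.names = FALSE),
                       file.path(out_dir, "true_exposures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(catalogs = catalogs, reference = reference, exposures = expo)
}

#' Generate every pipeline input into one directory
#'
#' Runs all generators under the config's seed and writes a
#' `truth.json` manifest recording the planted ground truth (surviving
#' variant keys, spiked neoantigen sequences, signature exposures).
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all generator outputs plus `truth`.
#' @export
generate_all <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- generate_reference(config, out_dir)
  variants <- generate_variants(config, reference, out_dir)
  pssms <- generate_pssms(config, file.path(out_dir, "pssms"))
  mutanome <- build_mutanome(reference$proteome, variants$missense)
  peptides <- generate_immunopeptidome(config, mutanome, pssms,
                                       out_dir = out_dir)
  sbs <- generate_sbs_catalog(config, out_dir)
  truth <- list(seed = config$seed,
                variants = variants$truth,
                spike = peptides$truth$spike,
                decoys = peptides$truth$decoys,
                sbs_exposures = as.data.frame(t(sbs$exposures)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reference = reference, variants = variants,
                 pssms = pssms, mutanome = mutanome,
                 peptides = peptides, sbs = sbs, truth = truth))
}
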