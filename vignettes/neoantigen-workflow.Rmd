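---
title: "Methods: a synthetic proteogenomic neoantigen workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic proteogenomic neoantigen workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscan)
```

This vignette documents the model behind each stage of the workflow,
the parameter choices of the synthetic-data generator, and the
numerical decisions that make the whole pipeline exactly reproducible.

## 1. Variant consensus and hard filters

Somatic SNV calls from several callers are merged per variant key
(chromosome, position, ref, alt). When multiple callers report the
same key, the record from the highest-priority caller is kept (default
priority: mutect2, varscan, strelka) and the variant allele fraction
is recomputed as `alt_depth / total_depth`, so the retained VAF always
agrees with the retained depths. Hard filters are all **strict**
inequalities:

| filter | threshold |
|---|---|
| VAF | > 0.05 |
| total depth | > 20 |
| alt reads | > 5 |

A variant sitting exactly on any boundary is removed, and
`filter_status()` reports every failed criterion, not just the first.
Mutational burden is `n_filtered / exome_size_mb` with a 30 Mb exome
by default.

## 2. Mutanome and window enumeration

`apply_missense()` substitutes one residue (validated against the
stated wildtype) at a 1-based position. `enumerate_mutation_windows()`
emits every length-`L` substring containing the mutated residue, for
`L` in {8, 9, 10, 11} (class I) and 15 (class II). Windows are never
truncated: an interior mutation yields exactly `L` windows of length
`L`; near a terminus only the windows that fit are returned. Each row
records the in-peptide mutation position, so for `DAKLGGVI` at
residues 91–98 with G→R at 95 the 91-start window is `DAKLRGVI` with
`mut_pos_in_peptide = 5`.

## 3. Binding model

Allotype motifs are position-specific scoring matrices (PSSMs): an
`L × 20` weight matrix over the amino-acid alphabet. A peptide's score
is the sum of its per-position weights, mapped to an affinity in nM by

$$\mathrm{nM} = 50000^{\,1 - \sigma(s/4)}, \qquad
  \sigma(x) = \frac{1}{1+e^{-x}}$$

which is strictly decreasing in the score and bounded in
(1, 50000) — the conventional affinity ceiling. Consensus prediction
registers `n_predictors` (default 3) copies of the donor PSSM set, the
first unperturbed and the rest with i.i.d. Gaussian jitter
(`sd = 0.15`) on the weights, and takes the **median** predicted nM,
mimicking consensus tools that aggregate disagreeing algorithms while
staying robust to one outlier. **Agretopicity** is the ratio
`wt_nM / mt_nM`; table values are rounded half-up.

## 4. Candidate scoring and ranking

Binders (`mt_nM < 500`, strict) are scored by

```
score = 1/mt_nM + wt_nM/mt_nM + gene_tpm * (wt_nM/mt_nM) + vaf/2
```

so absolute binding strength, agretopicity, expression and clonality
each increase priority, with expression weighting the agretopicity
term multiplicatively. Tables are split per (allotype, length), sorted
by descending score; ties break by lower mutant affinity, then
lexicographic mutant peptide, making every ranking fully
deterministic.

## 5. Immunopeptidome matching

Eluted-peptide records are kept at `fdr <= 0.01` (inclusive) and
deduplicated per HLA class. Allotype assignment is a deliberate
simplification of mixture-model motif deconvolution: each class I
peptide goes to the donor allotype whose length-matched PSSM scores it
highest (lexicographic tie-break; unassigned if no PSSM covers its
length). A peptide is called a directly observed neoantigen when it
(a) is a substring of a mutated protein, (b) spans the mutated
residue, and (c) is absent from the reference proteome — checked
against the concatenated proteome with a `#` separator so a single
fixed-string search suffices. Matches whose novelty rests only on an
isoleucine/leucine difference are flagged `il_ambiguous`, because mass
spectrometry cannot distinguish these isobaric residues.

## 6. Mutational signatures

SNVs are counted into the canonical 96 pyrimidine-centred
trinucleotide channels (purine-reference variants are
reverse-complemented). De novo extraction is Frobenius
multiplicative-update NMF with seeded multi-restart (default 10
restarts, tolerance 1e-10, up to 2000 iterations), keeping the
restart with the lowest reconstruction error; signature columns are
normalised to sum to 1. Extracted signatures are matched to a
reference by maximal cosine similarity, and per-sample exposures are
refit by non-negative least squares (`pracma::lsqnonneg`) and
normalised to proportions.

De novo NMF is only identifiable when samples differ in their
signature mixtures. The generator therefore draws exposures from a
symmetric Dirichlet with `exposure_alpha = 0.3`: samples are dominated
by one or two mutational processes, as real cohorts are. Dense
mixtures (large alpha) with few samples make exact factorisation
under-determined regardless of optimizer effort; recovery experiments
in the test suite use 30 samples of 10,000 SNVs for this reason.

## 7. The synthetic-data generator

All problem sizes are this package's own choices, picked so the full
workflow runs in seconds while every code path is exercised:

| parameter | default | rationale |
|---|---|---|
| `n_proteins`, `protein_length` | 150, 120–600 aa | room for interior and near-terminus mutations |
| `n_variants` | 40 | small but enough for designed failures |
| `n_fail_vaf/depth/alt` | 4 each | failures placed **exactly on** each filter boundary (VAF = 0.05, depth = 20, alt = 5), proving strictness |
| `mean_depth`, VAF prior | 100, Beta(2, 8) | typical tumour depths, subclonal-skewed VAF |
| `caller_overlap` | 0.8 | callers agree mostly, not perfectly |
| donor typing | A\*03:01, B\*07:02, B\*08:01 + DRB1\*03:01 | 3 class I + 1 class II ⇒ 13 ranked tables |
| class I / II peptides | 1500 (mode 9) / 500 (mode 15) | canonical eluted-length modes |
| `n_spike` | 3 | planted observed neoantigens |
| SBS | 4 signatures, 7 samples, 10,000 SNVs | compact catalogs |

Spiked peptides are each variant's **best-binding** legal class I
window (minimum predicted nM across the donor's class I allotypes),
since genuinely eluted peptides are by definition HLA-bound; a random
window could be a non-binder that no ranked table would retain. The
generator also plants near-miss decoys — the wildtype twins of every
spike and non-spanning windows of the mutated proteins — which the
matcher must reject.

Determinism: one global seed fans out through
`derive_stream_seed(seed, stream)` (a string-hash of the stream name,
reduced below 2^31), so adding a stream never perturbs the others.
Re-running the generator or the pipeline with the same configuration
reproduces every output file byte for byte, which the run manifest
verifies with md5 checksums.

## 8. Limitations

The PSSM predictors are not trained on experimental affinity data;
the simulated immunopeptidome has no contaminants, missed cleavages
or spectral noise; proteins are i.i.d. random sequences rather than
homologous families; and cohort-scale whole-genome inputs are out of
scope. The generator exists to provide exact, seeded ground truth for
verifying workflow logic — recovery rates measured on it say nothing
about performance on real tumour data.
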