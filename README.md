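# neoscan

A self-contained proteogenomic neoantigen identification workflow, as
used in tumour immunology studies that combine somatic variant calling,
HLA binding prediction and immunopeptidomics (mass-spectrometry
sequencing of HLA-eluted peptides). Every stage is implemented as an R
function, and the package ships a synthetic-data generator with known
ground truth so the entire workflow can be exercised, end to end and
offline, with exact expectations.

## The science

Tumours accumulate somatic mutations. A missense mutation changes one
residue of a protein; short fragments of the mutated protein
(8–11-mers for HLA class I, ~15-mers for class II) can be presented on
the cell surface and recognised by T cells as **neoantigens**. The
workflow identifies and prioritises them:

1. **Variant consensus** — somatic SNV calls from three callers
   (mutect2, varscan, strelka) are merged per variant with a caller
   priority order, then hard-filtered: VAF > 0.05, total depth > 20,
   alt reads > 5 (all strict). Mutational burden is reported as
   filtered variants per Mb of a 30 Mb exome.
2. **Mutanome** — each passing missense variant is applied to its
   protein and every mutation-spanning window of lengths 8–11 and 15
   is enumerated.
3. **Binding prediction** — position-specific scoring matrices (PSSMs)
   model each donor allotype; several jittered predictor variants are
   aggregated by median, mimicking consensus predictors. Scores map to
   affinities in nM via `50000^(1 - sigma(s/4))`. **Agretopicity** is
   the wildtype/mutant affinity ratio: a high ratio means the mutation
   created binding that the wildtype peptide lacked.
4. **Ranking** — candidates with mutant affinity < 500 nM are scored by
   `1/mt_nM + wt_nM/mt_nM + gene_tpm * (wt_nM/mt_nM) + vaf/2`
   (strong binding, high agretopicity, expression and clonality all
   raise priority) and ranked per allotype and peptide length.
5. **Immunopeptidome** — eluted-peptide identifications are filtered at
   FDR ≤ 0.01, deduplicated per HLA class, summarised (length
   distributions, motif-based allotype assignment) and matched against
   the mutanome: a peptide is a directly **observed neoantigen** if it
   is a substring of a mutated protein, spans the mutated residue, and
   is absent from the reference proteome (isoleucine/leucine ambiguity
   is flagged, since MS cannot distinguish them).
6. **Mutational signatures** — SBS96 catalogs are decomposed by
   non-negative matrix factorisation, matched to reference signatures
   by cosine similarity, and per-sample exposures are refit by
   non-negative least squares.

## Worked example

A wildtype protein carries `DAKLGGVI` at residues 91–98; a somatic
G→R missense hits residue 95. Applying the mutation and enumerating
the 8-mer windows that span it:

```r
library(neoscan)
set.seed(42)
res <- sample(aa_alphabet(), 120, replace = TRUE)
res[91:98] <- strsplit("DAKLGGVI", "")[[1]]
wildtype <- paste(res, collapse = "")
mutant <- apply_missense(wildtype, 95L, "G", "R")
cat(substr(wildtype, 91, 98), "->", substr(mutant, 91, 98), "\n")
#> DAKLGGVI -> DAKLRGVI

enumerate_mutation_windows(mutant, wildtype, 95L, lengths = 8L,
                           protein_id = "NOP58")[, c(3, 4, 6, 7, 5)]
#>   start end sequence wildtype_sequence mut_pos_in_peptide
#> 1    88  95 SIGDAKLR          SIGDAKLG                  8
#> 2    89  96 IGDAKLRG          IGDAKLGG                  7
#> 3    90  97 GDAKLRGV          GDAKLGGV                  6
#> 4    91  98 DAKLRGVI          DAKLGGVI                  5
#> 5    92  99 AKLRGVIL          AKLGGVIL                  4
#> 6    93 100 KLRGVILA          KLGGVILA                  3
#> 7    94 101 LRGVILAW          LGGVILAW                  2
#> 8    95 102 RGVILAWT          GGVILAWT                  1
```

The window starting at residue 91 is the mutant peptide `DAKLRGVI`
with the mutation at peptide position 5. Agretopicity and priority
score for a strong candidate (mutant 74 nM, wildtype 9940 nM,
98 TPM, VAF 0.16):

```r
agretopicity(wt_nM = 9940, mt_nM = 74)$ratio_rounded
#> [1] 134
candidate_score(mt_nM = 74, wt_nM = 9940, gene_tpm = 98, vaf = 0.16)
#> [1] 13298.2
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic
data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # generate all inputs + truth.json
Rscript analysis/02_consensus.R         # caller merge + hard filters
Rscript analysis/03_mutanome_ranking.R  # mutanome, binding, ranked tables
Rscript analysis/04_immunopeptidome.R   # elution QC + observed neoantigens
Rscript analysis/05_signatures.R        # NMF extraction + exposure refit
Rscript analysis/06_end_to_end.R        # one-call orchestrated run + manifest
```

Output of `analysis/02_consensus.R` and `analysis/04_immunopeptidome.R`
on the default simulation (seed 20260101):

```text
98 caller records -> 40 consensus variants -> 28 after hard filters
mutational burden: 0.933 mutations/Mb

1952 records at FDR <= 0.01; 1359 unique class I and 500 unique class II peptides
observed neoantigens:
     sequence protein_id      mutanome_id residue_pos mut_pos_in_peptide
1   DPEPEVEEW   PROT0016 PROT0016_p.H204D         204                  1
2 ECKCEWDWHMT   PROT0110 PROT0110_p.W233E         233                  5
3 NIQKYDMKTRF   PROT0028 PROT0028_p.F108Y         108                  5
```

All three peptides spiked into the synthetic immunopeptidome are
recovered, and `analysis/06_end_to_end.R` additionally checks that each
one also appears in a ranked candidate table. The orchestrator
(`run_end_to_end()`) isolates stage failures — a corrupt missense table
stops the mutanome branch but the variant-consensus branch still
completes — and writes `manifest.json` with an md5 checksum of every
output, so re-running an identical configuration is verifiably
byte-identical.

## Package layout

- `R/` — all computation: `variant_consensus.R`, `mutanome.R`,
  `binding.R`, `ranking.R`, `immunopeptidome.R`, `signature_fit.R`,
  `synthetic_data.R`, `pipeline.R`.
- `analysis/` — numbered workflow drivers (above).
- `scripts/acceptance.R` — standalone recomputation of the headline
  value.
- `tests/testthat/` — oracle-based unit tests plus end-to-end
  acceptance tests (`test-acceptance.R`).
- `vignettes/` — methods vignette describing the model, parameter
  choices and limitations.

## Limitations

The PSSM predictors and the simulated immunopeptidome are deliberate
simplifications: real binding predictors are trained on experimental
affinity data, real elution data contain contaminant peptides and
missed identifications, and real cohorts involve full-genome
sequencing at scales this package does not attempt to reproduce. The
generator's purpose is exact, seeded ground truth for verifying the
workflow's logic, not biological realism of the sequences themselves.
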