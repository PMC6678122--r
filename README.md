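# seedmir

Small-RNA profiling of developing seeds: miRNA discovery, expression
trends and target analysis.

## The problem

Developing seeds pass through distinct phases — embryogenesis, seed
filling, desiccation — under heavy post-transcriptional control by
miRNAs. A typical profiling experiment sequences nine small-RNA libraries
(3 phases × 3 biological replicates) and asks: which conserved miRNAs are
expressed, which novel miRNAs can be predicted from hairpin precursors in
the transcriptome, which miRNAs change between phases and how, what do
they target, and which functions are over-represented among those
targets. seedmir implements that entire chain as composable R functions
for people who want to run, audit or stress-test such an analysis without
opaque in-house scripts — every filtering rule, threshold and model is
explicit and configurable, and a synthetic-data generator with planted
ground truth makes each stage verifiable offline.

## What it computes

* **Preprocessing** — quality/adapter/polyA/length filtering with exact
  per-class accounting; collapse to unique tags with per-library counts;
  length distributions (`filter_and_trim`, `collapse_tags`,
  `length_distribution`).
* **ncRNA screening** — rRNA/tRNA/snRNA/snoRNA classification by
  substring match (≤ 1 mismatch, either strand) with fixed class priority
  (`classify_ncrna`).
* **miRNA identification** — conserved miRNAs by exact match to a
  miRBase-style mature reference; hairpin precursors recovered from the
  transcriptome with a bundled deterministic single-stem
  nearest-neighbour folding engine and evaluated by MFE, AMFE = MFE/len
  × 100 and MFEI = AMFE/GC%; novel miRNAs under explicit criteria (MFE ≤
  −18 kcal/mol, MFEI ≤ −0.85, ≥ 16 mature bases paired, ≤ 4 unpaired,
  one mature per hairpin locus); phase-presence Venn partitions
  (`match_conserved`, `fold`, `recover_precursors`, `predict_novel`,
  `phase_presence`).
* **Quantification** — TPM with a 0.01 floor for zeros; phase means;
  signed log2 fold changes; Welch tests on log2 TPM; DEmiR calling at
  |log2FC| ≥ 1 and P ≤ 0.05; trend classes bell/V/up-up/down-down;
  Pearson + PCA replicate QC (`tpm`, `de_table`, `classify_trend`,
  `replicate_qc`).
* **Targets** — ungapped antiparallel complementarity scoring with G:U
  wobbles as half-mismatches, positional rules (none at 10–11, no
  adjacent mismatches in 2–12, ≤ 2.5 penalties in 1–12, ≤ 4 total) and a
  duplex-MFE ≥ 75%-of-perfect filter, scanned by compiled code
  (`score_site`, `duplex_mfe`, `scan_targets`).
* **Enrichment** — upper-tail hypergeometric tests of DEmiR-target genes
  against the transcriptome background, BH FDR within each GO/KEGG
  family (`enrich_terms`).
* **Orchestration** — `run_pipeline()` chains the stages from FASTQ to
  TSVs; `simulation_config()`/`synthesize_inputs()` build a fully
  specified synthetic experiment; `ddct` and `profile_correlation` cover
  the qPCR-comparison arithmetic.

## Worked example

Generate a small synthetic experiment and run the pipeline:

```r
library(seedmir)

cfg <- simulation_config(rng_seed = 42, phase_depths = 8000,
                         n_unigenes = 60, n_conserved_planted = 8,
                         n_novel_planted = 5,
                         profile_assignments = c(
                           "bell", "V", "up", "down", "phaseI_only",
                           "phaseII_only", "phaseIII_only", "flat",
                           "bell", "V", "up", "down", "flat"))
inp <- synthesize_inputs(cfg, "sim")
res <- run_pipeline(pipeline_config(
  fastq = inp$fastq, unigenes = inp$unigenes,
  mature_ref = inp$mature_ref, contaminants = inp$contaminants,
  go_annotation = inp$go_annotation,
  kegg_annotation = inp$kegg_annotation, out_dir = "sim/out"))

res$preprocess$stats[1, c("library", "n_raw", "n_clean", "retention")]
#>   library n_raw n_clean retention
#> 1  MpSI-1  8000    7275  0.909375

res$identify$records[1:2, c("id", "family", "arm", "origin", "total")]
#>               id family arm    origin total
#> 6 mpi-miR156a-3p MIR156  3p conserved   882
#> 3 mpi-miR159b-5p MIR159  5p conserved   657

subset(res$quantify$de, trend == "bell",
       c(id, log2fc_II_I, log2fc_III_II, trend))
#>                 id log2fc_II_I log2fc_III_II trend
#> 1   mpi-miR156a-3p    2.408508     -2.108701  bell
#> 6   mpi-miR167f-3p   19.724567    -19.724567  bell
#> 10 mpi-nmiR0002-3p    2.254320     -2.384385  bell

head(res$enrichment[res$enrichment$significant,
                    c("term", "name", "category", "k", "K", "fdr")], 2)
#>          term                       name category  k  K          fdr
#> 1  GO:0006281                 DNA repair       BP 20 20 3.231888e-07
#> 19    ko03450 Non-homologous end-joining     KEGG 20 20 4.309184e-07
```

The 9% of reads emitted as the four designed artifact classes are removed
(retention 0.909); the identified records carry per-library counts; the
DE table classifies each miRNA's phase trajectory — note the planted
bell-shaped profiles recovered as `bell`, and the phase-II-exclusive
miRNA showing the characteristic mirrored ±19.7 fold changes produced by
the 0.01 TPM floor; and the planted GO term ("DNA repair") and KEGG
pathway top the enrichment table. All stage outputs are also written as
TSVs under `sim/out/`.

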