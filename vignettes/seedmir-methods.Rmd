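---
title: "Methods behind seedmir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind seedmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmir)
```

seedmir reimplements, as a tested and reusable pipeline, the analysis chain
used in developing-seed small-RNA profiling studies: raw reads from nine
libraries (three developmental phases — embryogenesis, seed filling,
desiccation — with three biological replicates each) are filtered and
collapsed to unique tags, screened against contaminant ncRNA, matched to a
mature plant miRNA reference, searched for hairpin precursors in a unigene
transcriptome, quantified as TPM, tested for differential expression
between successive phases, and connected to candidate target genes and
enriched functional categories. This vignette explains each model, its
tunable parameters and their defaults, the synthetic-data generator that
makes the whole chain testable offline, and the design decisions taken
where the methodology left genuine freedom.

## Read filtering

The customary filtering step ("remove low-quality reads, reads with 5'
adapters or polyA tails, reads without 3' adapters, reads shorter than 18
nt") is usually performed by unpublished in-house scripts. seedmir declares
explicit replacements, applied in a fixed order so every removed read is
counted in exactly one class:

1. **Quality** — removed if more than 20% of bases are below Phred 20
   (`max_lowq_frac`, `min_q`).
2. **5' adapter** — removed if the last 8 nt of the 5' adapter occur within
   the first 10 positions.
3. **3' adapter** — the first exact occurrence of the adapter's first 8 nt
   (`adapter_k`) marks the insert end; reads without one are removed.
4. **polyA** — removed if ≥ 80% of the trimmed insert is A or it ends with
   ≥ 10 consecutive A (the source methodology names the filter but not its
   definition).
5. **Length** — inserts below 18 nt are removed; inserts above 30 nt are
   also removed, reflecting the 18–30 nt gel excision of the library
   protocol, and counted separately.

Retention is exactly `clean/raw`, and removal-class counts plus clean reads
reconstruct the raw count — an invariant the tests enforce.

## The bundled folding engine

Precursor evaluation needs a deterministic, desk-scale secondary-structure
model whose optimum is provably findable, so seedmir ships its own
single-stem nearest-neighbour engine rather than wrapping an external
folder (one can be substituted behind `fold()`'s contract — a dot-bracket
string plus an MFE). Structures are restricted to one stem-loop: a chain of
nested pairs (Watson–Crick and G:U) with at most `max_gap = 3` unpaired
bases per side between consecutive pairs, a terminal loop of at least
`min_loop = 3` bases, and no multibranching. Energy is the sum of stacking
terms from a 6×6 table shipped as a plain-text fixture
(`stack_energies.tsv`, Turner-style ordering of magnitudes) plus loop
penalties linear in loop size (`hairpin: 4.5 + 0.3·size`,
`bulge/interior: 2.0 + 0.5·size`, kcal/mol). The open chain scores 0, so
MFE ≤ 0 always.

Two properties motivated this model. First, it is *exactly enumerable*: the
test suite checks the dynamic program against a brute-force enumerator that
generates every admissible chain of pairs and scores it with an independent
energy function (practical to ~32 nt; beyond that the structure count grows
exponentially — about 10⁵ chains at 30 nt and 3×10⁶ at 40 nt — so longer
sequences, up to 60 nt, are checked against an independent plain-R
implementation of the recurrence instead). Second, a single stem is the
object of interest: a pre-miRNA *is* a stem-loop, and restricting the
search space means a random sequence scores much weaker than a genuine
hairpin, which sharpens the MFEI criterion below.

The stacking table is constructed so that every stack containing a G:U
wobble is weaker than the same stack with the wobble replaced by its
Watson–Crick counterpart. This guarantees — and the tests assert — that a
wobble-containing miRNA/target duplex can never be more stable than the
duplex with the perfect complement, which keeps the target-prediction MFE
ratio in [0, 100].

## Precursor recovery and hairpin metrics

For each mature locus (exact occurrence in a unigene, sense strand only,
1-based inclusive coordinates) symmetric windows of 60–300 nt in 20-nt
steps are folded. Because a mature miRNA sits at the *end* of its hairpin,
any symmetric window wide enough to contain the full hairpin necessarily
carries unstructured flank on the other side; computing per-length metrics
on the raw window would dilute them arbitrarily. The chosen window is
therefore trimmed to the span of the outermost base pair (extended to
contain the mature) before length, GC%, AMFE and MFEI are computed; the
window minimizing MFEI among those with the mature wholly inside one arm is
kept. The defining identities, enforced on every emitted precursor, are

- AMFE = MFE / length × 100 (kcal/mol per 100 nt),
- MFEI = AMFE / GC%, with GC on the 0–100 scale.

Arm assignment: 5p if the mature ends at or before the last 5'-side paired
base, 3p if it starts at or after the first 3'-side paired base; a mature
overlapping the terminal loop disqualifies the window. A conserved
precursor is accepted when more than 10 reads (`anchor_min`) anchor —
i.e. map fully inside — the 5p and/or 3p arm.

`precursor_stats()` reports the arithmetic mean of each per-precursor
metric. For MFEI the mean of per-precursor ratios and the ratio of mean
AMFE to mean GC% differ in general; both are returned (`mean_mfei`,
`mfei_of_means`), with the mean of ratios as the headline number.

## Novel miRNA prediction

The usual transcriptome-based predictors are cited "with default settings"
that are not printed anywhere, so seedmir declares its criteria explicitly
in `novel_criteria()`, all configurable: mature length 18–26 nt; at least
16 mature bases paired within the hairpin (G:U counts as paired); at most 4
unpaired mature bases; precursor MFE ≤ −18 kcal/mol and MFEI ≤ −0.85; a
minimum of 5 reads across libraries for a tag to be considered at all
(low-count tags carry no reliable evidence and would dominate runtime); and
the same read-support requirement that defines a putative precursor in the
conserved branch — more than 10 reads anchoring the 5p and/or 3p arm. The
anchoring requirement matters in practice: without it, any 5-read
background tag whose random neighbourhood happens to fold acceptably would
be promoted to a miRNA.
MFEI ≤ −0.85 is the classical discriminator between miRNA precursors and
random or coding sequence, and under the single-stem model random windows
rarely reach it with 16+ mature bases paired.

Tags are processed in order of decreasing total count, and hairpin loci are
claimed greedily: once a precursor interval is assigned (conserved
precursor loci are pre-claimed), any later tag mapping inside it is treated
as a fragment or variant of that hairpin rather than as an independent
novel miRNA. This one-mature-per-locus resolution is how read-cluster-based
predictors behave, and without it every abundant degradation fragment of a
real hairpin would be re-reported as a separate discovery. A tag mapping to
several unigenes yields several precursor records under one id
(`mpi-nmiRNNNN-5p/3p`, numbered in discovery order).

## Quantification, DE calling and trends

Expression is transcripts per million: count / total clean reads of the
library × 10⁶, with zero counts floored at 0.01 so fold changes stay
finite. Before flooring, TPMs over all clean tags of a library sum to
exactly 10⁶ (tested). Phase expression is the arithmetic mean of the three
replicate TPMs; the two successive comparisons (II vs I, III vs II) yield
signed log2 fold changes.

The source methodology states thresholds (absolute fold change ≥ 2,
P ≤ 0.05) but not the test behind its P values. seedmir declares **Welch's
two-sample t-test on log2 TPM** across replicates, two-sided, with no
multiple-testing correction for DE (the thresholds are raw-P by
specification); with zero variance in both groups the P value is defined
as 1 for equal means. Published fold-change tables in this field print
signed, antisymmetric values (e.g. +8.49/−8.49 for expression confined to
the middle phase) with sub-2 "fold changes" among significant calls, so the
printed quantity is interpreted as the log2 ratio and the threshold as
|log2FC| ≥ 1. A DEmiR is significant in a comparison iff both conditions
hold; the DEmiR set is the union over the two comparisons. Trends follow
from the signed significant changes: (+,−) bell, (−,+) V, (+,+) up-up,
(−,−) down-down, exactly one significant change single-up/-down, none ns.
Note that the TPM denominator of published tables is ambiguous (total clean
reads vs miRNA-matching reads), so printed fold-change *magnitudes* are not
expected to be bit-reproducible from printed counts; seedmir uses total
clean reads, as the methodology's wording says.

Replicate QC reports the 9×9 Pearson matrix on log2 TPM and the first two
principal components of the library × miRNA matrix (centred, unscaled
covariance PCA). On synthetic data the within-phase correlations exceed
between-phase ones and replicates cluster by phase with positive
silhouette; the *absolute* correlation level of the real study (≈ 0.999) is
not a target here, since a small planted miRNA panel has far fewer
stable-expression dimensions than a full transcriptome-scale tag set.

## Target prediction

Candidate sites are ungapped antiparallel duplexes of miRNA length
(position 1 = miRNA 5' end; the site is read on the mRNA sense strand).
Per-position penalties: Watson–Crick 0, G:U wobble 0.5, mismatch 1. A site
passes iff total penalty ≤ 4; no run of more than two consecutive
mismatches; no adjacent mismatches within positions 2–12; no mismatches at
positions 10–11; penalties over positions 1–12 sum to ≤ 2.5; and the duplex
MFE is at least 75% of the perfect-complement duplex MFE. Two declared
interpretations, both configurable: the 10–11 rule forbids *mismatches*
but admits G:U (`gu_ok_1011 = TRUE` — the rule text distinguishes wobbles
from mismatches), and the 2.5 cap counts wobble half-penalties while the
adjacency rules count only full mismatches. Duplex energies use the same
stacking table as the folding engine plus a +4.1 kcal/mol initiation term;
mismatches interrupt stacking. Gapped sites (bulges) are out of scope: the
rule set counts positions, and pattern-matching screens of this kind are
ungapped.

The production scanner is compiled; the suite proves it site-for-site
identical (coordinates, scores, energies, verdicts) to a plain-R oracle
that evaluates every window with `score_site()`. Passing verdicts are
monotone under mismatch→match repairs by construction — every rule relaxes
and stacking only strengthens — and this is asserted property-style.

## Enrichment

Target genes of DEmiRs are tested per annotation family (GO MF/BP/CC,
KEGG) with the upper-tail hypergeometric probability
P(X ≥ k), X ~ Hypergeom(K, N−K, n), against the whole unigene set as
background; `stats::phyper` supplies the distribution and `stats::p.adjust`
the Benjamini–Hochberg step-up, applied within each family as the
categories are reported separately. Terms with fewer than 2 annotated
background genes are skipped. GO annotations are used as given, without
propagation to ontology ancestors — annotation tables here are flat
gene→term maps, and propagation would require shipping an ontology graph.

## The synthetic experiment

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs. Nine libraries of
10⁵ reads each; 150 unigenes of 400–1500 nt; 20 planted conserved and 12
planted novel miRNAs (mostly 21 nt, GC 40–65%), each embedded as a hairpin
— mature + randomized 8–20 nt loop + reverse-complement star offset by 2 nt
(the dicer-like overhang) — and refolded with the bundled engine at
generation time (redrawn until MFE ≤ −18, trimmed MFEI ≤ −0.85, at least
16 mature bases paired and at most 4 unpaired, so the planted truth
satisfies the discovery criteria it is meant to exercise). Planted conserved
matures appear verbatim in a miRBase-style reference among 30 decoys;
planted novel matures are absent from it. Expected counts per miRNA and
library are a log-uniform base abundance (100–600 reads at 10⁵ depth)
times a trend multiplier — bell (1,6,1), V (6,1,6), monotone (1,4,12) and
(12,4,1), phase-exclusive (4 in one phase), flat — then modulated by
lognormal replicate noise (σ = 0.15) and Poisson-sampled, i.e. mildly
overdispersed counts. Contaminant ncRNA fragments make up 8/4/6% of clean
reads in phases I/II/III; artifacts (no 3' adapter 2%, polyA 2%, low
quality 3%, short 2%) are emitted at fixed rates; the remaining background
consists of random unigene substrings with a 24-nt-dominant length
distribution whose secondary mode is 21 nt in phase I and 22 nt later.
Background draws that coincide exactly with a planted mature are redrawn,
so planted per-library truth counts are exact. Target sites (perfect or
single-wobble complements) are planted in non-precursor unigenes, and one
GO term plus one KEGG pathway are enriched by construction among the
target genes of trend-carrying miRNAs.

What the generator does *not* emulate — and what green tests therefore do
not demonstrate about real data: sequencing error models, isomiRs and
miRNA* reads as distinct classes, realistic ncRNA family structure,
multi-locus miRNA families sharing a mature, expression correlation
structure beyond the planted trends, and genome-scale transcriptome
redundancy. Recovery rates on this synthetic design (100% conserved recall
at these depths, ≥ 90% novel recall and trend recovery) are upper bounds
relative to real libraries.

Problem sizes in the shipped suite were chosen to keep the whole validation
desk-scale: unit and property tests run a 60-unigene, 8+5-miRNA experiment
at 8×10³ reads per library; the acceptance script runs the full default
design at 10⁵ reads per library.

## Numerical and degenerate-input conventions

Ties in the folding DP are broken deterministically (hairpin closure
first, then smallest inner 5' index, largest inner 3' index; outermost pair
by smallest coordinates), so equal-energy optima reproduce bit-identically.
All coordinates are 1-based inclusive; U and T are equivalent on input and
T is used internally. Empty inputs return empty, correctly-typed tables
rather than errors, except where the operation is undefined (summary of an
empty precursor set, TPM with a non-positive denominator, malformed FASTQ
— reported with the offending record index). Fixed seeds make generation
byte-identical and the analysis itself is deterministic, so a rerun of the
same configuration reproduces every output file exactly.

## Known limitations

The folding model ignores dangles, coaxial stacking and multiloops, so its
MFE values are not comparable in absolute terms with full
nearest-neighbour folders; only structure class and relative stability
matter here. Conserved identification is exact-match by design (as the
methodology prescribes), so isomiRs are invisible. Precursor search scans
the sense strand of an assembled transcriptome, not a genome. The DE test
has 3 + 3 replicates and raw-P thresholds; it is a reimplementation of the
published decision rule, not a recommendation — count-model methods
(negative binomial) are deliberately out of scope.
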