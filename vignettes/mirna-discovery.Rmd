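---
title: "miRNA discovery, annotation and quantification with mirprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA discovery, annotation and quantification with mirprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirprof)
```

## The problem

Plant microRNAs (miRNAs) are 21–24 nt regulatory RNAs excised from
stem-loop precursors. A small-RNA sequencing library from leaf tissue
contains, besides miRNAs, large amounts of rRNA/tRNA/snRNA/snoRNA
fragments and degradation noise. `mirprof` implements the standard
desk-top analysis of such a library for a species without its own genome
annotation, as is routine for medicinal and other non-model plants such
as curry leaf (*Murraya koenigii*):

1. **Cleaning** — adapter trimming, quality and length filtering,
   collapsing to unique tags, ncRNA contaminant removal.
2. **Conserved annotation** — homology of tags to a mature miRNA
   reference set (a miRBase-style catalogue) within a one-mismatch
   budget, with family summaries.
3. **Novel discovery** — mapping the unassigned tags to a (relative's)
   genome, excising candidate precursor windows, secondary-structure
   folding, stem-loop criteria, and the minimal folding free energy
   index (MFEI) gate.
4. **Target prediction** — plant-mode complementarity scoring with
   cleavage vs. translational-repression calls, an animal-mode
   (cross-kingdom) strict-seed scan, and MFE-weighted network export.
5. **qPCR quantification** — relative expression by 2^−ΔΔCt with an
   endogenous control and a calibrator, ANOVA/Tukey compact letters.

Every stage is validated against a seeded synthetic-data generator that
plants known miRNAs and designed hairpins, so recall, precision and
count accuracy can be measured against ground truth.

## Cleaning model

Reads are dropped when their **mean** Phred score is below Q30; the
"below Q30" rule admits several readings (mean, minimum, fraction of
bases) and the mean-based one, the common sRNA-workbench-style choice,
is the default and configurable (`min_mean_q`). The 3′ adapter is
removed at the leftmost position where at least `min_overlap = 8`
adapter-prefix characters match exactly; the 16–40 nt length filter is
inclusive at both ends. Contaminant matching is substring containment
of the tag in the contaminant record (tags are fragments of longer
ncRNAs), on both strands, with class attribution in the fixed priority
order rRNA, snoRNA, snRNA, tRNA so that multi-class matches are counted
deterministically. The cleaning report partitions the input reads
exactly — every read is surviving, low-quality, out-of-range or
attributed to one contaminant class — and this conservation is asserted
in the report constructor itself.

## Homology model

Conserved assignment is ungapped and substitution-only, matching the
"mismatch" vocabulary of published conserved-miRNA tables: the shorter
sequence slides along the longer, overhangs are free, and the minimum
Hamming distance over offsets is the mismatch count (ties: smallest
absolute offset, negative first). A BLAST-style seeded search is
deliberately replaced by this exhaustive scan — collapsed tag sets are
small, and exactness plus determinism matter more than speed here. A
tag is assigned to the reference with the fewest mismatches if that
minimum is within `max_mismatch = 1`; ties break to the
lexicographically smallest reference id, and a tag whose best score is
shared across families is flagged `ambiguous` rather than silently
resolved. Family member counts follow the convention of published
tables: one member per distinct mature sequence (names repeat across
sequence variants within a family).

## Fold engine and MFEI

The bundled fold engine is a nearest-neighbor-style energy-minimization
dynamic program over base pairs: G:C −3, A:U −2, G:U −1 kcal/mol, a
minimum hairpin loop of 3 nt, and a hairpin-loop closing penalty of
+4 kcal/mol. The closing penalty is what makes the model behave like a
thermodynamic folder where it matters here: without it, an imperfect
stem fragments into spurious single-pair hairpins and no imperfect
precursor would ever look like a single stem-loop. The engine is exact
for its parameterization (the test suite checks it against exhaustive
structure enumeration at small lengths) and deterministic. It is also
pluggable — any function returning a dot-bracket string and an energy
can be substituted — so a full thermodynamic engine can be dropped in
without touching the pipeline.

One property worth stating precisely: with wobble pairing disabled
(`gu = 0`) the model is exactly symmetric under reverse complementation;
with wobble enabled no model is, because complementation maps a G:U
pair to A:C, which cannot pair. Wobble stays on by default for
biological fidelity.

MFEI follows the standard definition: AMFE = (|MFE|/length) × 100 and
MFEI = AMFE / GC%, with GC content on the 0–100 scale computed over the
full excised window. The printed formula in the source literature for
this index is typographically garbled ("×100% GC content"); the
AMFE/GC% reading is the one that reproduces the 0.70–0.98 magnitude
range that published precursor tables show, and |MFE| is used so that
MFEI is nonnegative as those tables print it. Genuine precursors
typically score MFEI ≥ 0.70, above tRNAs (≈0.64), rRNAs (≈0.59) and
mRNAs (≈0.62–0.66), which is what makes the gate informative.

## Novel-miRNA calling

Mapping is an exhaustive substitution-only scan on both strands
(default budget 0 mismatches — synthetic genomes are exact; up to 2 for
cross-species mapping). Around each hit two windows are excised,
`[start − 150, end + 20)` and `[start − 20, end + 150)`, so that a
hairpin on either arm is captured whole in at least one window; the
flank length is an artifact default (the tools named in the literature
do not publish theirs) and is configurable. Minus-strand windows are
reverse-complemented so the mature always appears in read orientation.

The stem-loop criteria are evaluated **locally**: the mature's
stem-loop is delimited by walking the nested chain of pairs outward
from the nearest terminal loop, through bulges, stopping at multiloop
branch points. A 190-nt window's flanks always fold into something, so
any whole-window single-structure demand would reject every real
precursor; the local reading implements "a single stem-loop on the path
containing the mature". Pass requires ≥ 16 of the mature's bases paired
within that stem, ≥ 18 stem pairs, no overlap of the mature with the
terminal loop, and no unpaired run longer than 4 nt inside the mature.
These thresholds are package defaults, logged in every candidate table;
on random genomic windows the pass rate at defaults is a few percent,
while designed hairpins with up to 2 stem mismatches pass by
construction.

Calls are gated on MFEI ≥ 0.70 (inclusive) and collapsed read count
≥ 5. The copy-number gate is stated ambiguously in the source
literature (discovery vs. target-prediction stage); it is applied at
both, separately configurable. Multiple loci of one mature collapse to
the maximum-MFEI locus, and names are assigned `mko-miRN<k>-<arm>` in
descending read-count order.

## Target prediction

Plant-mode scoring adopts the psRNATarget-style penalty scheme, since
the tool is named in the literature without parameters: mismatch 1.0,
G:U wobble 0.5, gap 2.0, all doubled within the seed (miRNA positions
2–13); hits require expectation ≤ 5.0, and the best site per transcript
is reported (ties to the 5′-most position). The scan itself is
ungapped: the gap penalty is carried in the configuration for
completeness, but at expectation ≤ 5 with a doubled seed the admissible
alignments are substitution/wobble dominated, and an ungapped scan is
exactly checkable against window enumeration. Silencing mode uses the
central-complementarity convention — a mismatch at miRNA positions 9–11
predicts translational repression, otherwise cleavage (wobbles count as
paired); the mapping from scores to published cleavage/translation
labels is not specified in the literature, so this documented rule is
the package's convention.

Animal-mode (cross-kingdom) scanning requires perfect Watson–Crick
complementarity at seed positions 2–8 (wobbles disqualify), then
filters on duplex hybridization energy. The literature's "minimum free
energy ≥ −25" filter is read as |ΔG| ≥ 25 kcal/mol (i.e. ΔG ≤ −25) —
the literal reading would admit the weakest duplexes and reject the
strongest — but the literal rule is available via
`literal_energy_rule = TRUE`. Duplex energy is the optimal non-crossing
antiparallel pairing under the same pair energies as the fold engine,
with unpaired bases free; it is ≤ 0, deterministic and symmetric in
argument order.

## qPCR quantification

Per replicate, ΔCt = Ct(target) − Ct(reference) normalizes against the
endogenous control (the U6 role); ΔΔCt subtracts the calibrator's mean
ΔCt, and fold change is 2^−ΔΔCt. Per-miRNA summaries use the mean ΔΔCt
— the geometric mean of replicate folds — so the calibrator's summary
fold is exactly 1 by construction. When a `biological_replicate` column
is present, technical replicates are averaged within biological
replicates first; both layers exist because published protocols
describe both "two biological × three technical replicates" and plain
triplicates. Letter groups come from one-way ANOVA on log10 folds,
Tukey's HSD at α = 0.05, and the standard insert-and-absorb
compact-letter-display, with letters assigned in descending-mean order
so output is deterministic. Fold changes are strictly positive;
under-expression relative to the calibrator is representable only on
the log scale, which is why summaries carry `log10_fold`.

## The synthetic-data generator

`simulation_config()` + `simulate_library()` emulate an adapter-ligated
plant sRNA library: every read is a planted conserved mature, a planted
hairpin mature, a random fragment of a labeled ncRNA contaminant, or
random noise, each with the 3′ adapter appended (QIAseq-style
`AACTGTAGGCACCATCAAT` by default) and uniform Q40 quality. The default
noise length distribution is shaped like a real plant library — 24 nt
the modal class at 9.52%, then 21/22/23 nt at 4.94/4.92/4.79% — so the
length-distribution stage has something realistic to summarize.
Planting is exact-copy: truth-table class counts match the
configuration exactly, which is what makes recall/precision/count-error
assertions sharp. `build_genome()` plants designed hairpins
(mature + loop + mismatched star, either arm, either strand) into a
random background at stated coordinates.

What the generator does **not** emulate: sequencing errors (an
error-free library is what the collapsed-tag pipeline assumes; a
substitution model would only blur the exact-count assertions), UMIs,
ligation bias, degradome reads, or realistic quality-score profiles.
Passing tests therefore demonstrate the correctness of the pipeline's
logic and arithmetic on its stated model, not robustness to platform
artifacts.

## Numerical choices and degenerate inputs

* Tags, assignments, hits and calls are always emitted in a
  deterministic order (documented sort keys), so identical inputs give
  byte-identical TSV output.
* All comparisons are done in uppercase DNA space (U→T); display
  surfaces convert back to RNA where the field prints RNA.
* Empty inputs return empty, correctly-typed tables; malformed records
  raise errors naming the offending record; an all-A sequence folds to
  the empty structure with MFE 0; MFEI is undefined (an error) at GC%
  of 0 or 100.
* Excision windows shorter than tag + 2·min_loop are discarded with a
  message; truncated hairpins then fail the paired-base minimum rather
  than being mis-scored.

## Problem sizes

The test suite runs libraries of 300–2000 reads against genomes of
10–20 kb and oracle comparisons at n ≤ 15 (structure enumeration),
200 × 25 (homology) and 600 nt (target windows); the acceptance script
runs a 10,000-read library against a 50 kb genome with 20 planted
conserved miRNAs and 3 planted hairpins. These sizes were chosen so the
whole validation runs in minutes on one core while every assertion
stays exact; all generators scale to larger studies by changing the
configuration only.

## Known limitations

* The bundled fold engine is a simplified nearest-neighbor model: good
  enough to rank hairpins and reproduce MFEI magnitudes, not a
  substitute for full thermodynamic parameters when absolute energies
  matter; published precursor MFEI values are carried as data, not
  recomputed.
* E-values in the conserved table are opaque metadata from the original
  database search and are never recomputed.
* Homology is ungapped; a conserved miRNA differing from its homolog by
  an indel would be missed, consistent with the mismatch-only
  definition used for the catalogue.
* GO/KEGG annotation, enrichment and network visualization are out of
  scope; the package exports a standard edge list for graph tools.
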