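---
title: "TRA repertoire clonotyping: model, simulator and design choices"
author: "TRArep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TRA repertoire clonotyping: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRArep)
```

## The analysis this package implements

T-cell receptor alpha (TRA) chain amplicon sequencing characterizes the
T cells infiltrating a tissue by three facts per transcript: which TRAV
gene was used, which TRAJ gene was used, and the amino-acid sequence of the
CDR3 junction between them. TRArep implements that analysis end to end:

1. **Segment assignment.** Each merged read is aligned locally
   (Smith–Waterman, affine gaps) against every reference TRAV and TRAJ
   segment; the best-scoring segment of each class that passes a score and
   identity threshold becomes the call.
2. **CDR3 extraction.** The CDR3 is delimited by two conserved residues of
   the IMGT numbering: the 2nd-CYS at position 104 (last codon of the V
   region proper) and the J-PHE at position 118, which is followed by a
   glycine. Both anchor codon coordinates are carried as explicit reference
   metadata and mapped onto the read through the gapped alignment; the
   junction is reported inclusive of both anchors (the AIRR "junction"
   convention), so every productive CDR3 starts with C and ends with F.
3. **Clonotype collapse.** Reads with identical (TRAV, TRAJ, CDR3 amino
   acids) are one clonotype — literal string identity, no fuzzy clustering,
   nucleotide variants of the same amino-acid junction merged. Clonotypes
   are counted, ranked by copy number and expressed as percentage
   occurrence frequencies; a V×J usage matrix is computed alongside.
4. **Invariant T cells and sharing.** MAIT and iNKT cells are flagged
   purely by their canonical V–J pairs (Trav1–Traj33 and Trav11d–Traj18;
   the duplicate-locus "d" suffix is absorbed by an alias table). Clonotypes
   shared between the two sensitization groups ("Ni-Pd", "Cr-Pd") are the
   exact key-set intersection of the two profiles, with no frequency
   threshold.

Because no sequencing data were deposited for the study design this mirrors,
the package also ships a ground-truthed simulator that generates the reads
the analysis consumes, which turns every pipeline property into a testable
claim.

## Productivity

A read is *productive* when its junction length is a multiple of three, the
translation contains no stop codon, the first and last residues are C and F,
and — when the read covers the codon after position 118 — that codon encodes
glycine. Nonproductive reads are excluded from clonotype counting but
tallied (`nFailed`), since only reads with a deduced amino-acid CDR3 can
enter a CDR3-keyed clonotype definition. Frequencies are therefore
percentages of *productive counted reads*, not of all sequenced reads; the
alternative denominator is a one-line change but would make frequencies of
distinct samples incomparable whenever their failure rates differ.

The glycine check is applied only when the read covers that codon: the
motif is a property of the germline J segment, and requiring it on a
truncated read would discard otherwise complete junctions.

## The simulator: what it emulates and what it does not

`simulateSample()` draws a clone set and realizes reads from it:

* **Skewed abundances.** Background clone frequencies follow a geometric
  law (ratio `abundanceParam`, default 0.95 over 200 clones — top
  background clone ≈ 4.5%) or a symmetric Dirichlet. Inflamed-tissue
  repertoires are oligoclonal; the geometric default reproduces the "few
  dominant clonotypes over a long tail" shape seen in such data.
* **Junctional diversity.** Each clone is `V[1..len−trimV] + insert +
  J[trimJ+1..]` with trims up to 6 nt per side and a non-templated insert
  up to 12 nt, redrawn until the junction is in frame and stop-free
  (productive-only by default; `nonproductiveFraction` injects
  frame-shifted clones when wanted).
* **Invariant spike-ins.** One MAIT (TRAV1–TRAJ33) and one iNKT
  (TRAV11–TRAJ18) clone at 5% each by default.
* **Cross-group sharing.** `simulateCrossReactiveExperiment()` plants
  `round(sharedFraction · nClones)` clones with identical keys in both
  groups, including one dominant (TRAV8D-1, TRAJ49) clone at 20% and one
  (TRAV5-1, TRAJ37) clone at 15% — the "high proportion" cross-reactive
  clonotypes the analysis is designed to surface. All other keys are
  distinct between groups by construction, so the planted intersection is
  exactly the expected one.
* **Sequencing error.** I.i.d. per-base substitutions at `errorRate`
  (default 0.003, a realistic post-merging MiSeq figure), every mutated
  offset logged in the ground truth. Read counts per clone are multinomial
  in the true frequencies (fixed sequencing yield per sample); reads are
  the clone sequence truncated at `readLength` (default 300 nt, the MiSeq
  2×300 read span) and are never padded — merged amplicon reads are
  variable-length, and the configuration is rejected if any junction plus
  its following glycine codon is not covered.

Deliberately **not** modeled: PCR amplification bias, chimeras, indel
errors, quality-score structure, UMIs, and the TRB chain. Passing tests
therefore demonstrate correctness of the analysis logic under a clean
substitution-noise model, not robustness to library-preparation artifacts.

The mock reference (`buildMockReference()`) deserves the same honesty: its
segments are unrelated random sequences with correct anchor structure
(Cys codon + stop-free 3' tail for V; stop-free 5' head + Phe-Gly motif
for J). Real germline V genes form homologous families, so real-data
assignment is harder than the mock makes it; the mock is a correctness
harness, not a difficulty benchmark. Runs on real data must supply a real
IMGT-derived FASTA (gene-level, one sequence per gene) with anchor
coordinates, and should record which reference snapshot they used.

## Alignment parameters and numerical choices

* Scoring: match +2, mismatch −1, gap open −4, gap extension −1 (a gap of
  length L scores −4 − L); thresholds `minScore = 40`, `minIdentity =
  0.85`. These are forgiving at 1% substitution error on segment overlaps
  of ≥ 60 nt while rejecting unstructured sequence (a random 30-mer pair
  scores well under 40).
* N bases score as mismatches against everything, including N.
* Ties between segments resolve to higher identity, then to the
  ASCII-smaller gene name, so assignment is reproducible.
* Co-optimal alignment *paths* are tie-broken toward the ungapped path:
  when the returned optimal path contains an indel, the best ungapped
  alignment is also computed and used whenever it reaches the same score.
  Junction-adjacent indels otherwise make anchor mapping unstable for
  reads whose trimmed junction happens to echo reference bases.
* Anchor mapping through a gapped alignment fails the read (reason
  `anchor_missing`) if an anchor codon is outside the aligned reference
  interval or interrupted by an indel; frame inference across
  junction-proximal indels is unreliable and is not attempted.
* The chosen V must start on the read before the chosen J; in a conflict
  the lower-scoring side is dropped (`low_score`).
* Coordinates are 1-based and inclusive throughout, the R/Bioconductor
  convention; reference FASTA headers (`gene|class|anchor`) carry the
  1-based start of the anchor codon.

## Problem sizes used by the tests and the acceptance script

The shipped checks run the simulator at the scale of one sample of the
emulated study: 200 clones × 20,000 reads for recovery checks (error 0 and
0.01), 10 clones × 3,000 reads across 5 seeds for cross-group sharing, and
60 clones × 4,000 reads across 5 seeds for invariant detection. These sizes
give binomial standard errors small enough that every bound tested is
meaningful, and each run completes in minutes on a single core.

Two measured interpretations are worth stating. "Correct assignment" under
noise is scored at the V/J segment level: a substitution inside the CDR3
changes the amino-acid key of a read with probability roughly proportional
to junction length (about 20% of reads at 1% error for a 30-nt junction),
which is a property of the exact-identity clonotype definition, not an
assignment failure. Clone-frequency recovery at 1% error stays within
`3·sqrt(f(1−f)/n) + 0.01` of the truth because the same error process also
removes reads from the productive denominator; the residual deflation of a
5% clone is ≈ 1 percentage point.

## Known limitations

* Gene-level resolution only; alleles are collapsed and no allele calls
  are made.
* No diversity indices, rarefaction, or statistical tests of sharing
  enrichment — the outputs are tables meant for downstream tools.
* Whether the emulated analysis pooled Figure-level denominators per group
  is unknowable from the source; profiles here are per-sample
  (`profileFromClonotypeTable()` can rebuild pooled profiles by
  concatenating tables if needed).
* The simulator's junction lengths are shorter than typical murine TRA
  CDR3s (7–12 residues vs 10–15) because mock anchors sit near the segment
  ends; all contracts are length-agnostic.

## A worked example

```{r example}
ref <- buildMockReference(8, 8, seed = 1)
par <- SimulationParam(nClones = 10, nReads = 500, errorRate = 0,
                       sharedFraction = 0.3, seed = 42)
xp <- simulateCrossReactiveExperiment(par, ref)
profiles <- lapply(names(xp), function(s)
  buildClonotypes(annotateReads(xp[[s]]$reads, ref), s))
topClonotypeTable(profiles[[1]], k = 5)
findSharedClonotypes(profiles[[1]], profiles[[2]])[, -(1:2)]
```
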