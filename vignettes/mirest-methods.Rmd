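---
title: "mirEST: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirEST: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirEST)
```

## The problem

Mature plant microRNAs are strongly conserved: an orthologue in a new
species typically differs from a known mature by at most four nucleotide
substitutions, and it sits on one arm of a fold-back precursor (pre-miRNA)
of roughly 50–350 nt.  This makes homology search in expressed sequence
tags (ESTs) a productive discovery route when no small-RNA sequencing is
available: probe an EST collection with known matures, keep hits whose
surrounding sequence folds into a thermodynamically convincing hairpin, and
discard everything that looks like a protein-coding fragment or a repeat
artefact.

mirEST implements that workflow end to end as testable code.  The stages
are fixed: probe dereplication → both-strand homology scan → redundancy
collapse → protein-coding filtration → precursor excision and folding →
criteria screening → (optional) target prediction → per-family
neighbour-joining trees.

## Homology scan

Published pipelines of this kind use a seeded heuristic (BLASTN) followed
by a mismatch-count cut.  mirEST replaces the heuristic with an exact
ungapped Hamming scan of every window on both strands: for a ≤4-substitution
budget over ~21-nt probes this is strictly more sensitive than a seeded
search and has no tuning parameters.  Gapped matches are not considered
hits — a small substitution budget over the mature length *is* the
operative definition of homology here.  `N` never matches anything, so
dbEST-style ambiguity codes count against the budget.  Whether the original
EST studies scanned reverse strands is usually unstated; EST orientation is
arbitrary, so mirEST always searches both strands.

Redundant ESTs from the same gene are collapsed before folding: the region
around each hit (±200 nt) is globally aligned against every other
hit-bearing region of the same probe family, regions at ≥95 % identity over
≥90 % mutual length are single-linkage clustered, and the hit from the
longest EST represents each cluster.

## Coding filtration

The reference workflow removes protein-coding ESTs with BLASTX against a
protein database.  mirEST ships a database-free surrogate: a six-frame ORF
scan in which ORFs may start at AUG *or at a sequence edge* (ESTs are
fragments, so a truncated CDS has no start codon) and must end at a stop or
an edge.  An EST is called coding when its longest ORF reaches 80 amino
acids.  The threshold is a declared constant, not an inference of the
original BLASTX cut-offs (which are unpublished); on random 300-nt
background at 40 % GC it false-flags ≲5 % of sequences, and that chance
loss is visible in the benchmark recall below.  Users with a real
protein-homology screen can bypass the rule with a precomputed exclusion
list (`filter_coding(..., exclude_ids = )`).

## Folding model

Precursor windows are folded with a Zuker-style minimum-free-energy dynamic
program over a compact nearest-neighbour model embedded in the package:

* stacking free energies for the six canonical pair types (Watson–Crick
  plus G:U), in 0.1 kcal/mol integers, indexed in the standard
  reversed-inner-pair convention;
* hairpin, bulge and interior loop initiation tabulated for small sizes
  and extended by Jacobson–Stockmayer extrapolation
  (`1.75·RT·ln(n/n0)` at 37 °C);
* an interior-loop asymmetry penalty (0.5 kcal/nt, capped at 3 kcal);
* an affine multibranch penalty `a + b·branches + c·unpaired`
  (3.4 / 0.4 / 0 kcal);
* hairpin loops of at least 3 nt; interior/bulge loops capped at 30 nt
  (the classic MFOLD setting); no pseudoknots; `N` never pairs;
  dangling ends and coaxial stacking omitted as second-order for hairpin
  screening.

The table is the 37 °C / 1 M NaCl regime by construction; no
temperature or salt scaling is implemented, and exact reproduction of
MFOLD 3.5 energies is out of scope — every downstream threshold is
re-calibratable through `run_config()`.  Energies are computed in integer
tenths of kcal/mol, which makes "DP equals exhaustive enumeration" an exact
statement: `brute_force_mfe()` enumerates all valid non-crossing pair sets
and scores them with the same loop-decomposition evaluator
(`structure_energy()`), and the test-suite checks equality on hundreds of
short random sequences.  A Nussinov-style `max_pairing()` oracle backs the
structural tests.

Among equal-energy structures the DP prefers fewer pairs (the objective is
`energy·1024 + pairs`) and resolves remaining ties by a fixed traceback
order, so folding is fully deterministic.  Only the single MFE structure is
kept; suboptimal ensembles and partition functions are out of scope.

## Screening criteria

For each retained hit, candidate windows over a length ladder
(60–300 nt, clipped to the configured bounds and the EST) and two
placements (mature behind a 10-nt leader, mature before a 10-nt trailer)
are folded, and the best-MFEI structurally valid window is kept.  The
screen then evaluates:

1. mature on one arm of the hairpin (5p or 3p);
2. no unpaired run longer than 3 nt inside the mature on its own strand;
3. at most 6 mature positions unpaired against the star arm;
4. MFE ≤ −15 kcal/mol;
5. MFEI ≤ −0.7, with `MFEI = ((MFE/length)·100) / GC%`;
6. GC content within 20–70 %;
7. precursor length within 50–350 nt.

MFE/MFEI thresholds are "keep if at or below" — the published phrasing
("lower than −15 … were discarded") is ambiguous, and retaining *stable*
folds is the only reading consistent with the screen's purpose.  Criteria
1–3 put numbers on the hairpin-geometry conditions that the source
literature cites without constants; 3 nt and 6 mismatches are declared,
config-exposed decisions.  MFEI ≤ −0.85 raises a `high_confidence` flag
(strongly indicative of genuine miRNAs) but never filters, and a mature
starting with U is reported, never filtered on.  Simple tandem repeats
(primitive units of 1–6 nt, ≥3 copies, ≥12 nt span) are annotated as a
library-free stand-in for transposon-element masking; full library-based
repeat classification is out of scope.

Overlapping passing windows on the same EST are collapsed to the best-MFEI
representative: a probe that hits the mature region also hits the star
region on the opposite strand, and both describe the same hairpin.

## Target prediction

Plant miRNAs bind their transcripts with near-perfect complementarity, so
target prediction is an expectation-penalty scan: per miRNA position a
Watson–Crick pair costs 0, a G:U wobble 0.5, a mismatch 1.0 and a gap 2.0,
with penalties doubled in the seed region (positions 2–13).  Sites with
expectation ≤3.0 over at most one gap are reported, overlapping sites
deduplicated to the best-scoring.  Any non-Watson–Crick column at positions
10–11 — the slicing centre — calls the site as translational inhibition
rather than cleavage.  These constants are the published defaults of the
psRNATarget-style tool family, declared here as config-exposed package
constants; target-accessibility (UPE) scoring is omitted because it
requires ensemble folding, which is out of scope.

## Phylogenetics

Family trees are built from pairwise identity distances
(`d = 1 − matches/columns` under global Needleman–Wunsch alignment at
+1/−1/−2) with a hand-written Saitou–Nei neighbour-joining that breaks Q
ties towards the smallest index pair and clamps negative branch estimates
to zero (with a message).  A progressive multiple alignment is unnecessary
for NJ on identity distances, so none is computed.  NJ is exact on additive
matrices; the tests verify topology and path-length recovery against trees
drawn with `ape` and cross-check topologies against `ape::nj`.

## The synthetic benchmark

Real discovery runs depend on external databases, so the package's study
condition is synthetic: `benchmark_collection()` generates 30 planted
compliant precursors (random arm, strand, 0–4 probe substitutions, 0–4
duplex mismatches, 6–12-nt loops, 80–150-nt flanks), 100 background ESTs of
200–800 nt at 40 % GC (the average GC reported for *Brassica rapa*
precursors), 10 protein-coding decoys (≥100-codon ORFs) and 5
tandem-repeat decoys (≥24-nt runs).  A planted precursor is
`mature + loop + star + 2-nt overhang` (mirrored for 3p specs), the star
being the reverse complement of the mature with the requested number of
non-pairing substitutions kept away from the loop- and overhang-adjacent
positions, the 2-nt overhang mimicking the staggered DCL1 cuts.

"Compliant" is enforced, not hoped for: when a configuration is supplied,
the generator excises, folds and screens every planted EST and redraws a
plant's stochastic components until it passes (probes are drawn at
45–60 % GC so this converges quickly).  The truth table records every
planted coordinate, so recall and precision are computable without
re-inspecting sequences.  A passing candidate counts as a true positive
when its window overlaps the planted precursor region of its EST — a
star-side call still recovers the same hairpin.

What the generator does **not** emulate: realistic codon usage, sequencing
errors and quality values, UTR/intron structure, transposon libraries, and
the phylogenetic correlation structure of real EST collections.  Passing
the benchmark therefore demonstrates that the machinery is correct and
calibrated on its own terms, not that real-data sensitivity/specificity
will match.

At the default conditions (seed 17) the pipeline recovers 28 of 30 planted
hairpins (recall 0.93) at precision 1.0; the two misses are background-rate
false positives of the 80-aa ORF rule on planted host ESTs, i.e. exactly
the chance loss the coding filter's ≤5 % false-positive envelope allows.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive in all user-facing tables; internal
  representations are 0-based where convenient.
* `N` residues are legal input everywhere: they never match a probe, never
  pair, and are excluded from both numerator and denominator of GC.
* `mfei()` with zero GC returns `NA` and fails the criterion — never a
  division error.
* Window ties in excision go to the smaller (more negative) MFEI, then to
  the shorter window; screen criteria are evaluated on exact `<=`/`>=`
  comparisons, so boundary values (−15.0, −0.7, 20, 70) pass exactly.
* Queries longer than an EST simply produce no hit; an empty EST collection
  or a hit too close to the EST edge yields empty results, not errors.
* All randomness flows through explicit seeds; reruns with the same seed
  and configuration write byte-identical artifacts (the run log
  deliberately contains no timestamps).

## Problem sizes used by the test-suite

The folding oracle is checked on 200 random sequences of ≤12 nt (the
enumeration is exponential), the scan oracle on 20 probes × 50 ESTs at all
budgets 0–4, NJ exactness on 20 random 4–6-taxon additive matrices, and the
full benchmark at its native size (145 ESTs).  These sizes were chosen so
the whole suite exercises every contract in a few minutes on one core while
keeping each oracle exhaustive rather than sampled.

## Known limitations

* The energy model is a compact nearest-neighbour table, not a full Turner
  2004 parameterisation: no dangles, coaxial stacks, special hairpins or
  1×1/2×2 interior-loop tables.  Absolute MFEs differ from MFOLD/ViennaRNA
  by a few kcal on typical precursors; the screening thresholds are applied
  to the package's own energies and are config-exposed for recalibration.
* The ORF-length coding filter is a surrogate for protein-homology search;
  it cannot recognise short or frame-broken coding fragments.
* The tandem-repeat annotator finds exact simple repeats only, not diverged
  transposable elements.
* Identity-based NJ trees are descriptive, not model-based; no bootstrap
  support is computed.
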