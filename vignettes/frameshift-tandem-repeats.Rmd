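---
title: "Comparing tandem repeats across reading frames: methods and design"
author: "frameshiftTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing tandem repeats across reading frames: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frameshiftTR)
```

## The problem

The genetic code reads DNA in triplets, so inserting or deleting a number of
nucleotides not divisible by three shifts the frame and produces a radically
different protein. Tandem repeats (TRs) — arrays of approximately identical
sequence units — are both widespread in proteomes and unusually prone to such
frameshift events, and because their periodicity lives at the DNA level a
repeat in the main frame usually remains a repeat (of a different amino-acid
unit) in the shifted frames. `frameshiftTR` implements the machinery needed
to compare repeat content, composition and structural-annotation coverage
between reference proteins and the +1/−1 readings of the same coding
sequences, together with a synthetic data generator that makes the whole
chain testable with planted ground truth.

## Frame translation and fragmentation

A coding sequence is translated at same-strand offsets 0 (reference), 1
(+1) and 2 (−1); the antisense strand is never read, since a frameshift
re-reads the same message. Alternative frames are rich in stop codons, so
their translations are split into maximal stop-free fragments and only
fragments of at least `min_fragment_len` residues (default 60) are kept —
short debris between stops carries no analysable repeat. Reference
translations are kept whole after stripping the terminal stop; an internal
stop in a reference frame is unexpected, so the sequence is truncated at the
first stop with a warning rather than silently fragmented. Identical
fragment sequences within a set are deduplicated (first occurrence kept),
the in-package analogue of clustering input sequences at 100% identity.
Every fragment records its CDS, frame and the 0-based nucleotide offset of
its first codon (`nt_start`), which is what later allows repeats found on a
frameshifted fragment to be projected back onto main-frame codons.

## The repeat detector

Three detectors cover the unit-length spectrum, sharing one acceptance
criterion. For a candidate region and period $p$, the *phase-majority
consensus* assigns to each of the $p$ phases its most frequent letter (ties
broken alphabetically), and *purity* is the fraction of region positions
matching their phase's consensus letter. A region is acceptable at mismatch
tolerance $f$ when purity $\ge 1 - f$ (default $f = 0.1$).

- **Homorepeats** (unit 1) are maximal single-letter runs of at least
  `min_run` residues (default 5), purity 1 by construction.
- **Short-period arrays** (units 2–8) are seeded wherever two consecutive
  units agree at the tolerance, then extended greedily rightward to the
  largest interval that stays acceptable. The purity deficit is
  non-decreasing during extension, which bounds the lookahead; extension
  beyond a region's true end is possible while the accumulated budget lasts,
  so edges are afterwards cleaned: an end position is dropped while it
  mismatches its phase consensus or while its flanking $2p$-window is
  majority-mismatch. Copy-number minima are 2.5 for units 2–3 and 2.0
  above (short units need more copies to be convincing).
- **Long repeats** (units 9–100) are seeded by exact 5-mers recurring at a
  distance in range; the region grows unit-by-unit in both directions while
  each unit's identity to the running per-column majority consensus stays at
  or above `min_unit_identity` (default 0.5), a deliberately permissive
  growth rule in the spirit of profile-based long-repeat finders.

Every emitted region is then *reduced to its primitive period*: the unit
length is replaced by the smallest $p' \le p$ whose phase consensus on the
final interval is acceptable, and a consensus that is a whole-number
repetition of a shorter string is rejected as degenerate (note that a unit
such as `LKL` is primitive even though it has a weak string-period of 2 —
only divisor-length tilings count). This reduction rule makes the detector
agree, by construction, with the exhaustive smallest-period oracle
(`oracleSmallestPeriod()`), which simply tries every period up to half the
segment length; the test suite checks this agreement on 500 seeded strings
with planted arrays.

Overlaps between the detectors' candidates are resolved deterministically:
candidates are ranked by higher purity, then smaller unit, then smaller
start, and accepted greedily. A lower-ranked candidate overlapping an
accepted region is trimmed to its largest uncovered subinterval and
re-derived rather than discarded — without this, a short pure region at the
edge of a long array (e.g. an `LK` lead-in before an `LKL` array) would
eliminate the entire array. A trimmed remainder was never independently
seeded, so it must meet the full extension threshold $1 - f$, not merely the
emission floor; this keeps the final set consistent with the oracle.

The emission floor `min_purity` (default 0.7) exists mainly for the
long-repeat path, whose growth criterion is unit identity rather than
purity. No numeric thresholds for repeat finding are given in the study this
package accompanies, so all thresholds are exposed in `detectorConfig()`
and were calibrated once on the synthetic fixtures, not on any proteome.

## Groups, composition and motifs

Repeats are classified by unit length into five groups (1; 2; 3–8; 9–50;
> 50), following the structural convention that short units favour disorder
and long units fold into repeat domains. Composition profiles pool every
residue inside the TR intervals of a set — pooling, not per-region
averaging, matches the set-level frequency definition (count of an amino
acid over count of all residues in the set). Category summaries use the
partition hydrophobic {I,F,V,L,W,M,A,Y}, hydrophilic {S,T,H,N,Q}, negative
{E,D}, positive {K,R}, and singletons Gly, Pro, Cys; Cys is reported but is
typically omitted from polygon-style displays because it is rare in repeat
regions.

For motif clustering, each repeat is chopped into in-phase unit windows
(a final partial window ignored; at least two complete windows required) and
summarised as a unit_len × 20 per-position frequency matrix. The cyclic
phase of a repeat unit is arbitrary — `SRSRSR` and `RSRSRS` are the same
repeat — so matrix and consensus are rotated to the canonical phase, the
lexicographically smallest rotation of the consensus. The flattened vectors
are clustered with DBSCAN (Euclidean metric, defaults eps 0.15, minPts 5,
all exposed), separately per unit-length stratum: vectors of different unit
lengths have different dimensions and no natural alignment, so cross-stratum
clustering with padding was rejected as an interpretation. Clusters are
ranked by size with alphabetical tie-breaks; the headline tables keep the
top 15. The DBSCAN loop is implemented in the package (no suitable
dependency is used for it) and is checked in the tests against a separate
brute-force implementation of the definition on instances up to 200 points.

## Codon-level analysis

When a run of one codon $b_1 b_2 b_3$ is read in the +1 frame, its interior
codons become $b_2 b_3 b_1$ (−1: $b_3 b_1 b_2$). These rotations are
bijections of the 64 codons with order three, so each Arg codon has exactly
one preimage per shift: six codons feed arginine under +1, of which three —
GAG (Glu), TCG (Ser), GCG (Ala) — encode residues that dominate reference
homorepeats. That is the codon-level mechanism behind the arginine surge in
frameshifted repeats, and the package surfaces both the per-shift sets and
their union (the question of whether "alternative frames" means one shift or
both is genuinely ambiguous; `argSourceCodons()` answers either).

Codon usage of the regions that give rise to frameshifted homorepeats is
computed by projecting each homorepeat's residue span back to CDS
nucleotides and collecting the main-frame codons its span touches; a
homorepeat only counts if it overlaps at least `min_overlap_aa` (default 9)
main-frame codons — the "at least 9 residues of the reference frame" rule is
read literally as a count of overlapped codons. Frequencies are normalized
over sense codons; stop-codon counts are kept but carry no frequency.
Within a repeat's DNA units, a codon position is *conserved* when the codon
is identical across all unit copies and *variable* otherwise, and the
conserved-codon frequency is
$100 \cdot n_{cons} / (n_{cons} + n_{var})$. Note that a detected region's
maximal amino-acid interval may legitimately include DNA-variable codons —
e.g. a CAA codon extending a CAG-encoded poly-Gln run — so even
mutation-free fixtures need not score 100% on detected (as opposed to
planted) intervals.

## Annotation overlap statistics

External structure predictions (disorder, aggregation, transmembrane,
domains) enter as typed residue intervals; the predictors themselves are
out of scope and never run. Intervals of one kind are unioned per fragment
before intersecting with TR regions, so overlapping predictions are not
double-counted. Set-level coverage is total covered residues over total TR
residues (the length-weighted mean of per-region coverages, an identity the
tests verify). Reference and frameshift coverage distributions are compared
per group with a two-sided Welch t-test on per-region coverages — Welch
because nothing guarantees equal variances, per-region because the
per-region coverage is the natural sampling unit here (the alternative,
per-protein units, is not determinable from the study's description). Star
labels follow the usual mapping (**** < 1e-4, *** < 1e-3, ** < 0.01,
* < 0.05, ns otherwise); two constant samples are flagged degenerate rather
than given a p-value. Hydrophobic homorepeat histograms divide counts of
hydrophobic runs of each length by the count of *all* homorepeats in the
set, and summarise the 11–20 band (high aggregation potential) and the
≥ 21 band (long enough to span a membrane) as mean per-length frequencies;
the ≥ 21 band averages over lengths 21 up to the longest homorepeat
observed in the set.

## The synthetic generator

`generateCdsSet()` emulates coding sequences containing DNA-level repeats:
homopolymeric codon runs, short microsatellite-like arrays (units 1–24 nt)
and long tandem duplications (units 27–300 nt). Background codons are drawn
i.i.d. from a configurable usage table restricted to sense codons — uniform
over the 61 sense codons by default, a deliberately neutral choice since no
generative description of real repeat content is available; a dinucleotide
or slippage model is out of scope and documented as a limitation. Each CDS
receives every planted array once at distinct codon-aligned positions
(placement is sampled without replacement, so arrays never overlap and the
ground truth is unambiguous); arrays whose length is not a multiple of 3 are
followed by 1–2 random pad bases so the CDS stays codon-aligned, and a TAA
stop closes each sequence. Mutations are independent per-nucleotide
substitutions applied to each array at its own rate — the simplest model
that yields impure repeats for purity testing. For every array and every
frame in which its translation is stop-free, the ground truth records the
repeat's interval in that frame's full translation and the primitive
amino-acid period of the unmutated translation. A single seed drives all
randomness, making fixtures byte-reproducible.

What the generator does **not** emulate: realistic species codon bias,
slippage dynamics, repeat-length distributions of real proteomes, or real
disorder/aggregation annotations (the companion `generateAnnotations()`
produces random, optionally TR-biased intervals purely to exercise the
coverage machinery). Tests passing on these fixtures therefore demonstrate
correctness of the computations, not biological calibration; headline
proteome-scale figures from real data are outside what this package can
reproduce at desk scale.

## Numerical choices and degenerate inputs

Purity-threshold comparisons carry a 1e-9 tolerance so that ratios such as
9/10 compare correctly against `1 - 0.1` in floating point. Majority votes
break ties alphabetically; greedy extension prefers the rightmost valid
endpoint; regions are sorted by fragment, start and unit length, making all
outputs order-deterministic. Empty inputs are defined, not errors, wherever
a downstream stage can continue (empty fragment sets, empty region sets,
zero-count codon tables); operations whose result would be meaningless
(composition deltas of empty profiles, set coverage of an empty repeat set,
conservation of a single unit copy) reject their input with a message. CDSs
with ambiguity codes are skipped with a warning rather than guessed at.
CDS lengths not divisible by 3 are allowed; each frame simply ignores its
trailing partial codon.

## Pipeline scale

`runPipeline()` chains simulate/read → translate → detect → composition →
clustering → codon usage → annotation overlap, writes TSV/FASTA outputs and
a JSON manifest (seed, parameters, row counts — no timestamps, so reruns are
byte-identical). The shipped test and acceptance configurations use 6–30
sequences of 300–900 nt with 2–3 planted arrays each, sizes chosen so the
full suite exercises every stage, including the 500-string oracle
comparison, in about a minute on one core.

## Known limitations

- The detector is greedy; a pathological interleaving of two periodicities
  is resolved by rank, not globally optimally.
- Long-repeat growth needs one exact 5-mer pair per array; arrays mutated
  heavily enough to destroy every aligned 5-mer pair are missed (at the
  default tolerances this requires far more divergence than the emission
  thresholds accept anyway).
- Frameshift fragments below the length minimum are discarded before
  detection, so planted repeats inside short fragments are unrecoverable by
  design — the biological phenomenon of repeats "disappearing" in
  alternative frames; recovery tests lower the minimum to isolate detector
  behaviour.
- Motif clustering never compares repeats of different unit lengths, so a
  degenerate `GPGP` and a `GPP` array live in different strata even though
  they are biologically related.
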