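# frameshiftTR

Tandem repeats (TRs) are hotspots for frameshift mutations: because their
amino-acid periodicity is encoded at the DNA level, a repeat often survives a
+1 or −1 shift of the reading frame — but as an entirely different protein
sequence. `frameshiftTR` compares TRs between proteins read in the main frame
of their coding sequences (CDSs) and the +1/−1 readings of the same DNA. It
is aimed at protein-sequence analysts studying low-complexity regions,
repeat evolution and the products of frameshifted reading.

The package provides, end to end:

- **Frame translation** — each CDS is translated at same-strand offsets 0, 1
  and 2; alternative-frame translations are split at stop codons and only
  stop-free fragments of ≥ 60 residues are kept (configurable), mirroring how
  frequent alternative-frame stops erase repeat regions.
- **Tandem-repeat detection** — a self-contained detector covering
  homorepeats (unit length 1), short-period arrays (units 2–8, mismatch
  tolerant) and k-mer-seeded long repeats (units 9–100). A region spanning
  residues *[a, b)* at period *p* is accepted when its purity — the fraction
  of positions matching the phase-majority consensus — satisfies
  purity ≥ 1 − *f* (default *f* = 0.1), with at least two unit copies, and the
  emitted unit length is the smallest period meeting that criterion on the
  final interval. An exhaustive smallest-period oracle validates the
  detector in the test suite.
- **Length groups and composition** — repeats are classified by unit length
  (group 1: 1 residue; 2: 2; 3: 3–8; 4: 9–50; 5: > 50) and amino-acid
  frequencies are pooled per set as
  freq(aa) = count(aa in set) / count(all residues in set), with
  physico-chemical category summaries.
- **Motif clustering** — each repeat's per-position amino-acid frequency
  matrix, rotated to the canonical (lexicographically smallest) cyclic phase,
  is flattened into a vector and clustered per unit-length stratum with
  DBSCAN; clusters are ranked by size.
- **Codon analysis** — the cyclic codon rotation b1b2b3 → b2b3b1 (+1) /
  b3b1b2 (−1) models shifted reading of homopolymeric codon runs; the package
  enumerates, e.g., the six codons whose +1 rotation encodes arginine, codon
  usage in main-frame regions overlapped (≥ 9 codons) by frameshifted
  homorepeats, and the conserved-codon frequency
  100 · n_conserved / (n_conserved + n_variable).
- **Annotation overlap** — typed residue intervals (IDR, AR, EAR, TM,
  DOMAIN) from external predictors are intersected with TR regions; coverage
  distributions are compared between reference and frameshift sets with a
  two-sided Welch t-test, and hydrophobic homorepeat length histograms flag
  aggregation-range (11–20) and transmembrane-range (≥ 21) runs.
- **Synthetic data** — a generator plants homopolymeric codon runs,
  microsatellite-like arrays and long duplications into background CDSs with
  configurable codon usage, recording ground truth per reading frame, so the
  whole pipeline is testable without downloads.

## Worked example

```r
library(frameshiftTR)

# Glu/Ser/Ala homopolymer runs whose +1 readings are all arginine runs
cfg <- simConfig(n_sequences = 30,
                 planted_repeats = list(
                   plantSpec("homopolymer_codon", "GAG", 40),
                   plantSpec("homopolymer_codon", "TCG", 40),
                   plantSpec("homopolymer_codon", "GCG", 40)),
                 min_cds_len_nt = 900, seed = 5)
res <- generateCdsSet(cfg)
fr  <- translateCdsSet(res$cds)   # 60-residue minimum for frameshift fragments
fr
#> FragmentSet with 125 fragments (30 reference, 95 frameshift)
#>   lengths: 60-300 AA (median 92)

trs <- detectRepeats(fr)
trs
#> TRRegionSet with 213 regions
#>   by group: g1=211 g2=2 g3=0 g4=0 g5=0

lab  <- setNames(setLabels(fr), fragmentIds(fr))
df   <- as.data.frame(trs)
ref1 <- trs[df$group == 1 & lab[df$fragment_id] == "reference"]
fs1  <- trs[df$group == 1 & lab[df$fragment_id] == "frameshift"]
round(100 * aaComposition(fs1, fr)$aa["R"] -
      100 * aaComposition(ref1, fr)$aa["R"], 1)
#>    R
#> 49.1
```

The last number is the arginine surge in percentage points: reference
group-1 repeats are poly-Glu/Ser/Ala (Arg ≈ 0%), while the frameshifted
homorepeats read from the same DNA are about half arginine, because the +1
rotations of GAG, TCG and GCG (AGG, CGT, CGG) all encode Arg.

`rotateCodon("GAG", +1)` returns `"AGG"`; `argSourceCodons(+1)` lists all six
Arg-source codons with their main-frame residues.

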