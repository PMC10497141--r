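---
title: "The motif grammar of tandem-DBD nuclear receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The motif grammar of tandem-DBD nuclear receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nr2dbd)
```

## Background

Nuclear receptors (NRs) are modular transcription factors built from an
N-terminal A/B domain, a DNA-binding domain (DBD), a hinge, and a
ligand-binding domain (LBD). The DBD consists of two C4 zinc fingers: CI
with anchor spacing C-X2-C-X13-C-X2-C and CII with C-X5-C-X9-C-X2-C. Two
short boxes inside the DBD carry most of the functional specificity: the
**P-box**, the five residues that follow the third cysteine of CI (its
middle residue is the fourth cysteine), governs half-site recognition; the
**D-box**, the five residues between the first two cysteines of CII,
contributes to dimerization.

A small family of atypical receptors — the tandem-DBD receptors, or
2DBD-NRs — carries *two* DBDs in series upstream of a single LBD
(A/B–DBD–DBD–hinge–LBD). They occur across protostomes and deuterostomes
and fall into three groups: A and B, each spanning several phyla, and C,
restricted to nematodes. The family is recognizable from a compact motif
grammar rather than from full-length homology, and this package implements
that grammar as a deterministic, testable annotation pipeline.

## The grammar

The scanners implement, left to right along a protein:

* **Zinc fingers.** Exact anchor spacings for CI, CII and the atypical
  CHC2 finger (C-X6-C-X9-H-X2-C, third anchor histidine; found in some
  flatworm receptors but never in tandem-DBD receptors). Spacers are exact
  by default because the canonical geometry fixes them; a `tolerant` flag
  allows ±1 on the long middle spacer for the rare divergent finger.
* **DBD assembly.** Each CI is paired greedily with the nearest following
  CII within `max_inter_finger_gap` residues (default 30; the intra-DBD
  spacer is not fixed by the family definition, so the bound stays
  configurable). P- and D-boxes are the definitional 5-residue slices.
* **Architecture.** One DBD with an LBD is a typical receptor; DBD-only
  and LBD-only are the atypical single-module forms; two DBDs plus an LBD
  is the tandem-DBD architecture; neither module rejects the sequence.
  The inter-DBD **linker** is the residue count strictly between the two
  DBDs; in the family it falls in 17–22.
* **C-terminal extension.** The Grip box (G-box) follows the second DBD
  with general consensus RXGRZP (X one of F/R/G, Z hydrophobic) and
  group-specific variants: RXGRQ(P/S) in group A, the 5-residue KXGR(P/H)
  in group B, and the literal RDRRGP in *Aphelenchus avenae* group C.
  The **pre-Grip** is the stretch between DBD end and G-box: 5 residues in
  groups A/B, 8 in group C. Because the reference T-box spans 12 residues,
  a pre-Grip of at least 12 is scored as T-box-compatible — so tandem-DBD
  receptors never carry a T-box. Group A additionally conserves an `H`
  five residues after the G-box.
* **NTSS.** Three clade-specific N-terminal signature sequences of
  parasitic flatworm receptors are matched in the A/B domain:
  CNLGxKDRRP (trematode A1), TNDVTAMKEKTP (cestode A1), and
  (S/T)PExAFxQYQxR(M/S)EGQx (A2/A3).
* **LBD.** The 20-residue **Ti** signature
  (F/W/Y)(A/S/I)(K/R/E/G)xxxx(F/L)xx(L/V/I)xxx(D/S)(Q/K)xx(L/V)(L/I/F)
  is the computable LBD detector; the **AF2-AD core** (general
  Phi-Phi-x-E-Phi-Phi with group variants) is located nearest the
  C-terminus; and class I / class II dimerization residues
  (E5, E50, KR55, RK93 vs ED42, E50, R62, HRK90) are scored on an aligned
  LBD row. The call uses the strict discriminators — RK93 for class I,
  R62 for class II — because tandem-DBD receptors type as class I through
  E50 + RK93 while lacking KR55.
* **Classification and naming.** The **P-P module** pairs the two
  P-boxes (rendered with their anchor cysteines, e.g. `CEACKK-CEGCKG`).
  Four signatures are diagnostic: `CEACKK-CEGCKG` and `CEACKK-CEACKG`
  for group A, `CLPCKS-CEGCKK` and `CEACKS-CEGCKG` for group B. Group C
  has no signature — its module is highly variable — so it is gated on
  the Nematoda taxon flag. Names follow the rule-based nomenclature:
  species code + `2DBD-NR` + group letter + gene numeral + optional
  variant letter.

Degenerate positions everywhere use the three physicochemical classes
hydrophilic RKDENQ, neutral SGHTAP, hydrophobic YVMCLFIW, which partition
the 20-letter alphabet. An input `X` matches only wildcard positions,
never an anchor or a fixed consensus position.

All constants live in a single configuration (`default_config()`, YAML
mirror in `inst/extdata/config.yaml`), so divergent family members can be
accommodated without code changes.

## Coordinates and numerical choices

* All hit coordinates are 0-based, half-open; slicing is unambiguous and
  `end - start` is always a length.
* Overlapping finger matches are all reported; assembly consumes each
  finger at most once, leftmost first, which makes the pipeline
  deterministic.
* The CTE search window is 30 residues: observed pre-Grip lengths are 5
  and 8, so 30 is generous while excluding downstream false hits.
* The pre-Grip is measured from the last anchor cysteine of the second
  DBD's CII (the DBD end) to the G-box start. The reference alignments do
  not pin down the measurement origin, so this package documents its own
  convention; the synthetic generator uses the same one, which is what
  makes the 5/8 values exactly recoverable.
* When no group hint is available, `scan_gbox()` falls back to trying the
  general consensus first and then each group variant, returning the
  leftmost hit of the first pattern that matches.
* Group assignment uses Hamming distance over the ten P-box positions
  (the two invariant anchor cysteines contribute zero). The default
  tolerance is one mismatch; an exact tie between signatures leaves the
  sequence `UNCLASSIFIED` rather than guessing.
* More than two assembled DBDs classifies from the first two with a
  `MULTI_DBD` warning instead of aborting the run.
* Neighbor joining clamps negative branch lengths to zero with a message;
  distances are plain p-distances (1 − fraction identity of a global
  BLOSUM62 alignment, gap open 10, gap extend 1). Model-corrected
  distances are deliberately out of scope: the tree is a corroborator for
  the rule-based classifier, not an inference tool.

## The synthetic generator

`make_sequence()` assembles a protein directly from the grammar:
A/B filler (optionally ending in an NTSS), DBD1, linker (uniform 17–22 by
default), DBD2, pre-Grip + G-box + the conserved fifth residue, hinge, and
a 120-residue LBD carrying a Ti instance at a fixed offset, class-marker
residues at the default column map, and an AF2 instance at the
C-terminus. `make_panel()` emits the five P-P module situations plus four
decoys (typical single-DBD receptor, LBD-only, CHC2 protein, random
protein) with a row-aligned truth table.

Design choices worth knowing:

* **Filler is neutral-class minus C and H** (S, G, T, A, P). No filler
  residue can complete a zinc-finger anchor, begin a Ti window (which
  needs F/W/Y), or start a G-box (which needs R/K), so every embedded
  motif is recovered at exactly its generated coordinates. This is a
  simplification: real sequences contain cysteines and aromatic residues
  outside motifs, and scanning real proteins can produce overlapping or
  spurious candidate fingers that the greedy assembler must arbitrate.
  Passing round-trip tests therefore demonstrates correctness of the
  grammar, not robustness to compositional noise.
* The group-C template P-P module (`CDGCKS-CKSCSE`) is a synthetic
  stand-in at Hamming distance ≥ 2 from all four signatures: the real
  nematode module is too variable to have a consensus, and the stand-in
  exercises the taxon-gated classification path.
* The intra-DBD CI→CII gap defaults to 10 residues, comfortably inside
  the assembler's default bound.
* Sequence-level ground truth (`TruthRecord`) stores every realized
  parameter and motif coordinate, enabling exact field-for-field recovery
  tests.
* Clade-recovery tests build their panels from one base sequence per
  group plus a handful of neutral-for-neutral substitutions inside the
  DBD spans. With fully independent filler, within-group and
  between-group distances are statistically indistinguishable (the P-P
  signal is a few positions out of ~100), so a tree over independent
  draws would not be a meaningful check of the tree builder.

## Problem sizes used in the test suite

The shipped suite validates the scanners against brute-force
position-by-position oracles on 1,000 random 200-residue sequences
(cysteine-enriched so finger-shaped patterns actually occur), checks the
aligner against exhaustive alignment enumeration on pairs of length ≤ 6,
verifies neighbor joining against 20 random 5–8 taxon additive matrices,
and runs full parameter recovery on 100 synthetic positives (20 copies of
each of the five templates). These sizes give dense coverage while keeping
the suite fast enough to run on every change.

## Known limitations

* LBD detection is Ti-based. A receptor with a divergent Ti would be
  annotated DBD-only; there is no profile/HMM fallback.
* The class I/II profile requires a user-supplied alignment column map;
  the shipped map matches only the synthetic LBD layout.
* Gene numbering within a group needs an ordering. The biological
  numbering follows named phylogenetic subgroups, which is not computable
  from sequence alone; the default orders by P-P module in report order
  and can be overridden with a tree.
* p-distance NJ on DBD spans is a corroborator. It will not resolve deep
  splits reliably and is no substitute for model-based phylogenetics.

## A worked example

```{r example}
panel <- make_panel(1, seed = 42)
report <- annotate_sequences(panel$records,
                             nematoda = grepl("^C_", panel$records$id))
report[report$architecture == "TWO_DBD_NR",
       c("seq_id", "pp_module", "group", "linker_len", "gbox",
         "pre_grip_len", "tbox_present")]
```

Naming the classified records for one species:

```{r naming}
codes <- setNames(rep("Sm", nrow(panel$records)), panel$records$id)
name_records(report, codes)$names
```
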