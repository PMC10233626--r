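---
title: "Methods: hydrogen-bond motifs, superposition and latch sequence statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrogen-bond motifs, superposition and latch sequence statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latchkit)
```

## What the package models

Reverse gyrases couple a helicase module to a type IA topoisomerase
through a "latch", an insertion in the second RecA-like (H2) subdomain.
Across the family the latch ranges from a large globular domain down to a
minimal element: a two-stranded antiparallel β-sheet capped by a short
loop. `latchkit` implements the analyses used to characterise such
minimal latches: backbone hydrogen-bond detection, β-bulge-loop
classification, rigid-body superposition with displacement probes,
inter-region contact inventories, and sequence-level statistics of latch
regions (length clusters, net charge at pH 7, hydrophobicity, local
alignment identity/similarity).

Everything operates on tidy tables: a structure is a tibble of atoms, a
hydrogen-bond set is a tibble of donor/acceptor pairs, and every module
returns a tibble (or an object with `tidy()`/`glance()` methods), so the
pieces compose with dplyr pipelines.

## Hydrogen bonds and the loop taxonomy

Backbone N–H···O=C bonds are scored with the Kabsch–Sander electrostatic
model,
\[ E = 0.084 \cdot 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \ \mathrm{kcal\,mol^{-1}}, \]
with a bond accepted when \(E < -0.5\) kcal mol\(^{-1}\). Crystal
structures carry no hydrogens, so amide H positions are inferred first:
1.0 Å from N, opposite the preceding carbonyl (prolines and chain starts
get none). Candidate pairs are pre-filtered at N···O ≤ 5.2 Å and at least
two residues of sequence separation; both donor→acceptor directions are
scanned. The energy model (rather than pure geometry) was chosen because
it is reproducible on hydrogen-free X-ray models and matches the
secondary-structure literature.

Hairpins are assembled from antiparallel bridges — residues \(i, j\)
bridge when both \(HB(i{\to}j)\) and \(HB(j{\to}i)\) exist, or both
\(HB(i{-}1{\to}j{+}1)\) and \(HB(j{-}1{\to}i{+}1)\) — merged into
ladders; two same-chain strands joined by a loop of at most 8 residues
are reported as a hairpin motif.

The capping loop is classified by the Milner-White/Sibanda taxonomy with
residue *i* anchored at the **first residue of the loop span**:

| label | loop length | characteristic bond | second (shared) bond |
|---|---|---|---|
| β-turn | 4 | — | — |
| type-1 bulge loop | 5 | N–H(*i*) → C=O(*i*+4) | C=O(*i*) → N–H(*i*+4) |
| type-2 bulge loop | 6 | N–H(*i*) → C=O(*i*+5) | C=O(*i*) → N–H(*i*+4) |

Real minimal latches keep the type-2 label even when the second bond is
missing, so the default (*relaxed*) mode requires only the characteristic
bond and records the second bond's presence and N···O distance as
evidence; *strict* mode, for surveys, demands both. Loops outside 3–8
residues are refused with an explicit out-of-taxonomy error. Because the
quoted "5 Å distance" for an absent bond does not name its atom pair, the
classifier reports the heavy-atom N···O distance (and computes it whether
or not the bond is present).

## Superposition, probes and contacts

Atom pairings match residues by chain + author number + insertion code
(never by sequence alignment), then atoms by name; Cα-only is the default
mode because quoted r.m.s.d. values in the structural literature come
from molecular-graphics Cα fits. The optimal rotation is obtained by the
singular-value (Kabsch) method with reflection correction. Published
protocols rarely state their outlier handling, so `refine_superpose()`
iterates fit → reject residuals > 2.0 Å → refit, up to 5 cycles — an
approximation of `align`-style refinement; both the cutoff and cycle
count are arguments. Every result retains the full pairing, per-atom
residuals and rejection flags so a drifting value can be audited rather
than trusted.

Displacement probes (e.g. a tyrosine hydroxyl) are measured after fitting
on a separate selection, in the common frame. Contacts between two
disjoint selections are all heavy-atom pairs within 4.5 Å — a cutoff
wide enough to operationalise van-der-Waals contact between side-chain
methylene groups.

The packaged `tmaritima_domains.yaml` carries the named selections
(H1/H2, latch spans, topoisomerase, T3) for *T. maritima* reverse
gyrase. Only the latch boundaries are fixed by the deposited entries
(full latch 389–459, globular part 395–455, minimal latch 387–400); the
other subdomain boundaries are approximate working definitions, kept in
the versioned config precisely so they can be edited without touching
code. Measurements default to the single protein chain, matching
crystals with one molecule per asymmetric unit.

## Sequence statistics

Latch regions are defined by mapping the author-numbered span of the
reference structure through a multiple alignment: the reference residue
positions give two alignment columns, and each sequence's ungapped
segment between those columns (inclusive) is its latch region — possibly
empty. Net charge at pH 7 uses the counting approximation
\(q = \#R + \#K + 0.5\,\#H - \#D - \#E\) (His at pKa ≈ 6.5 counts one
half); it is additive under concatenation, which the tests exercise as a
property. Hydrophobicity is the arithmetic mean over a named scale; the
scale is a parameter because none is canonical for this purpose, with
Kyte–Doolittle as the default every report names.

Length clustering sorts the lengths and splits where consecutive sorted
values differ by more than `gap_threshold` (default 6, one more than a
5-residue histogram bin, so bins inside a dense cluster never split it).
On dense, realistic length sets this reproduces the three latch-length
groups; on artificially sparse inputs a single gap larger than the
threshold starts a new cluster, which is the documented behaviour rather
than a defect.

Local alignment is Smith–Waterman with affine gaps (Gotoh), implemented
in C++ with BLOSUM62 and open/extend 10/0.5 as defaults — the EMBOSS
`water` parameterisation, under the convention that a gap of length
\(L\) costs \(\mathrm{open} + L \cdot \mathrm{extend}\). Percent identity
and similarity use the full alignment length (gaps included) as
denominator; similarity counts columns with a positive substitution
score. Two independent checks guard the implementation: an exhaustive
brute-force reference that enumerates matched-column sets (exact on
every sequence pair up to length 6 over a 3-letter alphabet;
`sw_bruteforce_check()`), and agreement with
`Biostrings::pairwiseAlignment()` on random longer pairs.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be tested
against *constructed* truth, without downloading coordinates.

**Hairpins.** Strands are built residue by residue from internal
coordinates (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, C=O 1.231 Å,
standard angles; strand dihedrals φ = −139°, ψ = +135°). The β-turn
motif is a pure dihedral template found by numerical optimisation of
the Kabsch–Sander energies of its blueprint bonds over ideal backbone
geometry. For the bulge loops this over-idealisation turned out to be
counterproductive: with covalent geometry held rigidly at textbook
values, the full bond pattern (characteristic loop bond plus the
four-bond sheet register) could not be realised robustly, whereas real
bulge loops accommodate it through small covalent-angle adjustments.
The type-1 and type-2 templates are therefore stored as refined
backbone *coordinate* templates: starting from a real kinase β-hairpin
backbone, the coordinates were minimised once under restraints for
near-ideal covalent geometry, the blueprint hydrogen bonds at
favourable geometry (N···O ≈ 2.7–2.9 Å, near-linear N–H···O), explicit
penalties against incidental bonds that would extend the sheet ladder
into the loop, and the survival of every required bond across a fixed
set of noise draws. Bond lengths in the stored templates deviate from
ideal values by ≲ 0.02 Å. A related subtlety fixed the type-1 blueprint:
a doubly hydrogen-bonded (i, i+4) pair is itself an antiparallel bridge,
which would legitimately extend the ladder and shrink the detected loop
to three residues, so the type-1 template realises only the
classifier's required bond N–H(*i*) → C=O(*i*+4); the type-2 template
carries both of its characteristic bonds. All templates are validated
by requiring that the package's own classifier recovers the intended
label at zero noise. Noise is isotropic Gaussian, standard deviation
`noise_sigma` per coordinate, applied under a mandatory seed. Each
artifact ships its blueprint (intended label, bond list, seed); tests
compare against the blueprint, never against re-derived properties.

What these synthetic motifs do *not* emulate: side chains (beyond the
backbone), sheet twist variation, solvent, or the conformational
heterogeneity of real bulge loops. A pass on the synthetic suite
demonstrates that the detection and classification machinery is correct
at crystallographic noise levels, not that every natural bulge loop will
be labelled — real surveys should inspect the reported evidence
distances.

**Sequence sets.** Lengths are drawn uniformly within each planted
cluster range; residue composition is constructed so the charge formula
yields the planted sign (surplus Arg/Lys for positive, surplus Asp/Glu
for negative, balanced counts for neutral, His used in pairs to keep
planted charges integral), with the remainder drawn from neutral
residues. The default blueprint mirrors the study conditions for the
latch survey: 184 sequences, length clusters 13 (3 sequences), 59–82
(36) and 89–119 (145), and a 114/13/57 positive/neutral/negative split.
These generated sets share the real survey's summary statistics but not
its phylogenetic correlation structure — identities between generated
sequences are meaningless, which is why the survey tests check cluster
and sign recovery only.

## Numerical choices and edge cases

* Alternate locations resolve to the highest occupancy (ties → altloc
  `A`); waters and heteroatoms are excluded from residue counts; model 1
  only for multi-model files.
* Spans are 1-based, inclusive, in author numbering — the coordinate
  system used in publications (`Phe391` means author residue 391).
* `kabsch_superpose()` refuses collinear/coincident point sets
  (rank check) instead of returning a spurious rotation; rejection that
  empties a pairing raises a rejection-collapse error.
* Degenerate survey inputs: all-gap regions report zero length and `NA`
  span; unknown sequence letters contribute zero charge with a warning;
  empty sequences have no hydrophobicity (error) but zero charge.
* H-bond energies are invariant under rigid motion to < 1e-9 (tested),
  so superposition order never affects motif calls.

## Problem sizes used by the test-suite and acceptance script

Recovery statistics use 200 seeded hairpins per class at σ = 0.2 Å and a
single σ = 0 structure per class; the superposition oracle uses
20-point clouds (5 replicates) against a hierarchically refined
rotation grid; the alignment oracle enumerates all 1 092 sequences of
length ≤ 6 over {A, R, E} (597 k pairs, exact equality required); the
survey uses the 184-sequence default blueprint. These sizes were chosen
to exercise every code path with stable statistics while keeping a
complete run comfortable on a laptop.

## Known limitations

* The hairpin detector targets two-stranded antiparallel ladders; it
  does not assign helices, parallel sheets, or multi-strand topologies.
* Bulge-loop subtyping by dihedral conformation (the large natural
  variability of type-2 loops) is out of scope; classification rests on
  loop length and the characteristic bonds.
* Printed-value reproduction for the deposited structures requires
  coordinate files the package does not ship;
  `reproduce_latch_study()` runs the full comparison set from a local
  folder and reports skipped items explicitly.
* Domain boundaries other than the latch spans in the packaged config
  are approximate; users comparing other reverse gyrases should supply
  their own map.

## A worked pipeline

```{r example, eval = FALSE}
library(latchkit)

# synthetic structure with known truth
h <- build_hairpin(hairpin_blueprint(loop_length = 6, noise_sigma = 0.1,
                                     seed = 42))
classify_hairpins(h$structure)

# synthetic 184-sequence latch survey
seqs <- generate_sequences(seqset_blueprint(seed = 1))
survey <- charge_summary(tibble::tibble(id = seqs$id,
                                        region_sequence = seqs$sequence))
survey$counts
cluster_lengths(nchar(seqs$sequence))
plot_length_histogram(survey$table)
```
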