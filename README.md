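# latchkit

Structural and sequence analysis of the reverse-gyrase **latch** — the
insertion in helicase subdomain H2 that bridges to the topoisomerase
domain of these positive-supercoiling enzymes. Minimal latches reduce to
a two-stranded antiparallel β-sheet capped by a short loop, and the loop
chemistry matters: a 4-residue cap is a β-turn, a 5-residue cap a type-1
β-bulge loop and a 6-residue cap a type-2 β-bulge loop, distinguished by
their backbone hydrogen bonds (type 1: N–H(*i*) → C=O(*i*+4); type 2:
N–H(*i*) → C=O(*i*+5); both share C=O(*i*) → N–H(*i*+4), with residue
*i* the first loop residue).

`latchkit` is aimed at structural biologists who want those calls — and
the quantities that usually accompany them — reproducibly, from R:

* **Hydrogen bonds**: Kabsch–Sander electrostatic energy
  `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol on
  inferred amide hydrogens; bond if `E < −0.5`.
* **Motifs**: antiparallel bridge/ladder assembly, hairpin detection,
  relaxed/strict bulge-loop classification with per-bond evidence.
* **Superposition**: Kabsch (SVD) fits with iterative outlier rejection,
  displacement probes, heavy-atom contact inventories.
* **Latch sequence statistics**: region extraction through a multiple
  alignment, net charge at pH 7 (`#R + #K + 0.5·#H − #D − #E`),
  hydrophobicity, gap-based length clustering, Smith–Waterman (Gotoh,
  BLOSUM62, gap 10/0.5) identity and similarity.
* **Synthetic data**: ideal β-hairpins with blueprint hydrogen-bond
  patterns and sequence sets with planted length/charge composition, so
  the entire pipeline is testable offline.

Structures are tidy atom tibbles (read from PDB/mmCIF via bio3d), every
analysis returns a tibble, and fitted superpositions support
`tidy()`/`glance()`/`autoplot()`.

## Worked example

```r
library(latchkit)

# a noisy synthetic type-2 bulge-loop hairpin with known ground truth
h <- build_hairpin(hairpin_blueprint(loop_length = 6, noise_sigma = 0.1,
                                     seed = 42))
classify_hairpins(h$structure)[, c("label", "loop_length", "residue_i",
                                   "hb_i_to_i5", "hb_i_to_i4")]
#> # A tibble: 1 × 5
#>   label            loop_length residue_i hb_i_to_i5 hb_i_to_i4
#>   <chr>                  <dbl>     <int> <lgl>      <lgl>
#> 1 type2_bulge_loop           6         5 TRUE       TRUE
```

The label is the generator's intended class: a 6-residue loop whose
first residue donates its amide to the carbonyl five residues on
(`hb_i_to_i5`), the type-2 signature.

```r
# the printed minimal-latch region of T. maritima reverse gyrase
hairpin_loop_span("PSMRFSLEELIIPD", start = 387)
#> # A tibble: 1 × 4
#>   loop_start loop_end loop_length loop_sequence
#>        <int>    <int>       <int> <chr>
#> 1        391      396           6 FSLEEL

net_charge(c("PSMRFSLEELIIPD", "PKFRIEKEDLILPD"))
#> [1] -2 -1
```

A 6-residue loop capping strands of four, and net charges of −2 and −1
for the engineered and the natural minimal latch — the values the charge
formula assigns these sequences at pH 7.

```r
# synthetic latch survey: 184 sequences, planted composition recovered
seqs <- generate_sequences(seqset_blueprint(seed = 1))
cluster_lengths(nchar(seqs$sequence))
#> # A tibble: 3 × 4
#>   cluster min_length max_length     n
#>     <int>      <int>      <int> <int>
#> 1       1         13         13     3
#> 2       2         59         81    36
#> 3       3         89        119   145
```

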