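# Domain map for T. maritima reverse gyrase (author numbering, chain A).
# Only the latch span is fixed by the deposited structures (full latch
# 389-459; the globular part deleted in the minimal-latch construct is
# 395-455, leaving the 14-residue minimal latch 387-400). The remaining
# subdomain boundaries are approximate working definitions for named
# selections and can be edited without touching code.
version: 1
reference: tmaritima_rgyr
regions:
  helicase: "A:1-586"
  h1: "A:1-232"
  h2: "A:233-586"
  latch_full: "A:389-459"
  latch_globular: "A:395-455"
  latch_minimal: "A:387-400"
  h2_minus_latch: "A:233-388,A:460-586"
  all_minus_latch_full: "A:1-388,A:460-1104"
  all_minus_latch_minimal: "A:1-386,A:401-1104"
  topoisomerase: "A:587-1104"
  t3: "A:775-950"
hbond_cutoff: -0.5
contact_cutoff: 4.5
atom_mode: CA
reject_cutoff: 2.0
max_cycles: 5
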