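# Conserved motifs of the vertebrate light-strand replication origin.
# motif 1: strictly conserved stem motif; motif 2: 5' base of the stem,
# one mismatch tolerated to catch lineage variants (e.g. GCCAG).
OL_motif1:
  pattern: CTTCT
  max_mismatches: 0
OL_motif2:
  pattern: GCCGG
  max_mismatches: 1
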