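description: canonical vertebrate order to the derived dual-CR rhacophorid order
start:
  labels:
  - 12S
  - V
  - 16S
  - L(UUR)
  - ND1
  - I
  - Q
  - M
  - ND2
  - W
  - A
  - 'N'
  - OL
  - C
  - 'Y'
  - COI
  - S(UCN)
  - D
  - COII
  - K
  - ATP8
  - ATP6
  - COIII
  - G
  - ND3
  - R
  - ND4L
  - ND4
  - H
  - S(AGY)
  - L(CUN)
  - ND5
  - ND6
  - E
  - CYTB
  - T
  - P
  - CR
  - F
  strands:
  - H
  - H
  - H
  - H
  - H
  - H
  - L
  - H
  - H
  - H
  - L
  - L
  - H
  - L
  - L
  - H
  - L
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - L
  - L
  - H
  - H
  - L
  - H
  - H
  anchor: 12S
end:
  labels:
  - 12S
  - V
  - 16S
  - L(UUR)
  - ND1
  - I
  - Q
  - M
  - ND2
  - W
  - A
  - 'N'
  - OL
  - C
  - 'Y'
  - COI
  - S(UCN)
  - D
  - COII
  - K
  - NCR
  - ATP6
  - COIII
  - G
  - ND3
  - R
  - ND4L
  - ND4
  - H
  - S(AGY)
  - ND6
  - E
  - CYTB
  - CR1
  - ND5
  - CR2
  - T
  - L(CUN)
  - P
  - F
  strands:
  - H
  - H
  - H
  - H
  - H
  - H
  - L
  - H
  - H
  - H
  - L
  - L
  - H
  - L
  - L
  - H
  - L
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - H
  - L
  - L
  - H
  - H
  - H
  - H
  - H
  - H
  - L
  - H
  anchor: 12S
steps:
- type: tdrl
  block:
  - 31
  - 39
  retention:
  - second
  - first
  - first
  - first
  - first
  - second
  - second
  - first
  - second
  note: formation of the LTPF tRNA cluster
- type: tdrl
  block:
  - 31
  - 35
  retention:
  - second
  - first
  - first
  - first
  - first
  note: ND5 shift downstream of the control region
- type: tdrl
  block:
  - 36
  - 37
  retention:
  - second
  - first
  note: LTPF to TLPF swap
- type: replace
  from:
  - CR
  - ND5
  to:
  - CR1
  - ND5
  - CR2
  to_strands:
  - H
  - H
  - H
  note: CR duplication retaining both copies
- type: replace
  from:
  - ATP8
  to:
  - NCR
  to_strands:
  - H
  note: degeneration of ATP8 into a non-coding region
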