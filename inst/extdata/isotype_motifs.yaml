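# Constant-region motifs used for isotype classification of heavy-chain
# reads. "N" positions are wildcards (excluded from mismatch counting); for
# IgG the bases observed at the three wildcard offsets determine the
# subclass. One mismatch is tolerated anywhere outside wildcard positions.
max_mismatches: 1
motifs:
  IgM: CAAATGTCTTCCCCC
  IgA: CCATCTACCCACTGA
  IgG: NACANCCCCATCNGTCTATCC
igg_subclasses:
  IgG1:  [G, C, T]
  IgG2a: [A, G, G]
  IgG2b: [A, C, A]
  IgG3:  [A, G, T]
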