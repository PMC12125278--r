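# Framework / CDR region map for the packaged Vh186.2 stand-in.
# Coordinates are 0-based half-open nucleotide positions on the germline,
# contiguous and covering the whole sequence; each region is a whole number
# of codons in the declared reading frame.
name: Vh186.2_synthetic
frame: 0
regions:
  - {region: FR1,  start: 0,   end: 90}
  - {region: CDR1, start: 90,  end: 105}
  - {region: FR2,  start: 105, end: 147}
  - {region: CDR2, start: 147, end: 198}
  - {region: FR3,  start: 198, end: 294}
  - {region: CDR3, start: 294, end: 327}
  - {region: FR4,  start: 327, end: 360}
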