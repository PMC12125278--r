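>Vh186.2_synthetic reconstructed Vh186.2/IGHV1-72 V region with canonical NP-response junction; synthetic stand-in, not the IMGT reference
CAGGTCCAACTGCAGCAGCCTGGGGCTGAGCTTGTGAAGCCTGGGGCTTCAGTGAAGCTG
TCCTGCAAGGCTTCTGGCTACACCTTCACCAGCTACTGGATGCACTGGGTGAAGCAGAGG
CCTGGACAAGGCCTTGAGTGGATTGGAAGGATTGATCCTTATAGTGGTGGTACTAAGTAC
AATGAGAAGTTCAAGAGCAAGGCCACACTGACTGTAGACAAACCCTCCAGCACAGCCTAC
ATGCAGCTCAGCAGCCTGACATCTGAGGACTCTGCGGTCTATTACTGTGCAAGATATGAC
TACTACGGTAGTAGCTACTTTGACTACTGGGGCCAAGGCACCACTCTCACAGTCTCCTCA
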