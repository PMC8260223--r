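>Aim2_5UTR_annotated
TTCCTGTCCTGTCTGCCGCCATGCTTCCTTAACTAGCTGCTAGGTTTTTTCCTTGTCGTGATGAAATCCACCCTCATGGACCTGTAAGTAAAATGTAGACTTGCATAGAGTGCTGTAATCTTACGGCCGAGGTTTCTTTTCAGGCTGATCCTGGGACTGTGAG
>Aim2_5UTR_unannotated
TATATCTAAAATACCTCTGGTTGAGACCTCACAGCTGGAGGAGAAACTCTGCTGAGGCTTGTAAAAAGGAAACTGAAAACTAGCATTTGCTTGGGCAGAGCCTTAATATATAATTATTTTGCCCCAGCATCAGGGTTTAGGACTCAGCTATAGGGCCAGGACTAGCCAAGCTTCAAAGTGAAAGAAGATAGTTGAGAGTACTTTCTGCTTTCTGTCTCCCAAGACCTGATTTTCATGATTTTCATGTCCTACTACTCATAGTGAAAATCTTTGTGAGGCGGATGGTTTGAACTCTCAGGACATACACCAGTCCCTGAGTTGAGAACTAAGGCTGCTTTGGAGAGAAGAAAATCCCCTGAGGTAAGTAGACTTGCATAGAGTGCTGTAATCTTACGGCCGAGGTTTCTTTTCAGGCTGATCCTGGGACTGTGAG
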