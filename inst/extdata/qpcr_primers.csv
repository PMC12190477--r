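gene,forward,reverse
IFNB1,CTTGGATTCCTACAAAGAAGCAGC,TCCTCCTTCTGGAACTGCTGCA
IFIT3,CGGAACAGCAGAGACACAGA,CGGAACAGCAGAGACACAGA
TNF,CTCTTCTGCCTGCTGCACTTTG,ATGGGCTACAGGCTTGTCACTC
TNFAIP3,GAAGCTTGTGGCGCTGAAAA,GAACGCCCCACATGTACTGA
ACTB,GCACTCTTCCAGCCTTCCTT,AATGCCAGGGTACATGGTGG
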