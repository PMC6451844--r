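>synthetic_snoRNA_1
CTGGTTACAACAGAGATGCGGCGGGCACCTGCAAACGGTGCTCGTTGGCAGACTCAAGAATATTCTAACACGGCGCGGTGTAAGCGACTATGCGGCTCAAACGAGAGCCTCACTCAGTCATTACGCAGAG
>synthetic_snoRNA_2
TGAAACAATGATGACCTAAACCAAGTATGCTCGGTCCGCACCAAGTCTATCACCGGGGTATTAATGCCGCCTACTGCAGGCCGTATCCAACCCGACAGCCCCCCCCCCAG
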