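>synthetic_rRNA_1
AGAAGTCTTGGAGCGTCATGACTGGCAAGGATATCAGTTCGCTTTTTGAGTGCTAACTATCGGTATAGGGGCGATCTTAAAGTGTCTTATATTGACCTTGAGTAAAGCCGTCATAGTTTGGTTGTGTCGTCGAACCATAGCTTAATTATTTGTGCGTCAACACCAATTCCAGATGGTGCAAGTATATCACCCGGATAACCCGCTTGTTTCGGGCCCAGGTGTATACGCGCAGTGTAGTCCAAGATATGATAGCGGGTCCAACAAAGGCCGACATGAGTGTAACGGGCTATTATTGTTAAA
>synthetic_rRNA_2
AGGCTCAGATCGCCCGCCAAGCCACCTGTTACTCTGAATCAACGGAGTAATGAGACTTTGATCGACGGTCGACCCTTGTTATACAGTCTCACTATTTCAGCTAAAGGTCTGATACGTTGCCCTAAGAACGTGCCGGTCCCGACGTATTTCAGCCGCCGTGTTATGTTCACAGCCGTTGGTAATAAGCTTACTCTCCCCGTTTATGCCAACAACACCTTTG
>synthetic_rRNA_3
GCGCCTAACGCCATTTTACCTAATAACCATTTGCTGCAGTCATTCCCCAGCCGCCGGTGTAAAATTGCTCAGTGCGCTTTCGTAGCCTCAGTAACCGGCGAGATCGCGCTGGGCCTACCGCTCCAACAGGACTGAGCTAAAACGGCCTGGGACTTTCGCATCCATACACCTCGTAAGCGC
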