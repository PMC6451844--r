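>synthetic_tRNA_1
AAATGCGCGGTCAGTACTTTTAGTTAAGGTGGTGCGCAACGACATGCTGCGTCTGGTACAATCGAAAACATTGCGG
>synthetic_tRNA_2
ATAAGAACAGTTGCAATGCGGATCGAGAAGGCACTTCATCTAAGCCGCTTTGAGGTGTGCACCGTTATCTCCGTATAAGAAC
>synthetic_tRNA_3
TAGGGGATTTAGACAAGACTCACGTAGGAGGATGAACCGGTTACAGCTCGTTGTGAATCCGGCCAGGTGTTCGG
>synthetic_tRNA_4
ACCGGGCAACGCTCTGATAATTTTCAGAATTTGACCTGCCCGTTGAATGGAGAAGCTGCGATACTGCCGCTTCTACCTTTGTTAAATTTT
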