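>synthetic_rRNA_like_1
TAGTTGTGCTAACTTGCGCAATGGACTTCCGAAAGGTAGGGGCGCAAAATTACCGCCTGGCGCTAAAGAGGCGGGCCATGTCCGTGGTGTTTCACTCCAGGCGTGTCCCTTTCCTACTGAGTCCTACTCGTACGCTGGTGGCGGAGTGCAAGGCCGAGCATCTCAGACACGGTCCACTTACCCCTTGGACCTGCATAGAGATGCCAGTATCACGGCCGCCCCGAGACTGTCCCAGGAGACGGCGGATCGATCACGTTCGTGATAGACACAGTAACCAAATCTCTCACCGTCGGCATATCGATTAAAGCCCTTCGTGCGATGAGTCAGCGGGTCCCGCTGCATGACTCTCACGGCGATGATCAGCTCCCTCGGAGGCGCATCGAGGGGAGGGGCGACGGTAACCATTATTTTTCTAAAGGT
>synthetic_rRNA_like_2
GTGAATGTCTGGAGTGGCCGGCATAAACGTAGGAAAGGGAATGCAGGACTGGTGGGCTCCACCTCATCCGGAAAGCCGATTCCCGGGACTGACCCTCGACTGCCAAACATCAAGGGCCACACCCACCGCAGGCCCACGAACGGTAAGGCGGTTGGTGTCGCATTCGATACGTAGAGGGCCAGCGTTCTTCATTTAGTGTCAACAAACATCCGCTAGCTACGCCACTGTAGGCCCAGTTTTTCGGTGATACTAGTTGGAAGTATGAAGCAGCTCTCCAGGAGCGTCCGCCAACACCCAACGTATTTCACCGCAATCGCCACAAGGATGTACCCCCTTCCACGAATCGGGGGCTGCTGCCAGTTAGGCGCTTGAGGTGAGGG
>synthetic_rRNA_like_3
TACTACTCCCGCGAGGGCGCACGTCGCTGCAGATCATGTTCGAGTGCTCCGACCGCGGCGTAGTGTCTCGTATCGCGGTCTAAAGAGAGGCCTCTCGCCAGATCAGACGACGGGAGCTATGAGCCAGCTGGCTCAGAGTCCTCGCGTGGCCGAGGCTGCGCGAGATTCTGCGTTAGGTTATGTAGTCATGGCACTAAGCGGCGTTCCCCACTGTTCACATATTGTAAGTACTCGCGCGGGGCACAGGCAAACACGTCTTTCAGCAAGACATGGACCCGGCTGTGTATATTACAGGCCTTC
>synthetic_tRNA_like_1
CGTCCCGTGTCGCTGAGATCACCTTCATTCAGTATCGCAATCACCGGGCGCGAACGTCGCCACGTACCATCTTAGG
>synthetic_tRNA_like_2
ATCTCGAACCCGCTCCAGGGCACAAAAAGTTCGCGTTCCTTTCCGTAGGTACTACTGCCCCCACGTGAGCACGC
>synthetic_tRNA_like_3
TACTCCACTAGTAACTCAACCAGCTCCAGGCACGCCGGCGCGATATTGCGGGGTCTTCCTAGGCACGTCTCGCCAACCCTTTTAT
>synthetic_snRNA_like_1
GCAGGTGGGCGAACGAGCTCTAAGGATCAGGACTACTTCTTTCGATTTGTCCAAGGATATTAAAACCTGGCATGGTCTCTACTGACGGTTTTGTAATCAAAGACTTGTGCGCCTCCGATGTCAACCCCCTCCTCTGGACAGAGTGAACGCGGAGTGGGGC
>synthetic_snRNA_like_2
GTTTTTGCAGGGAAGCGGGGACGTCGGGTCCGCCAAGCTTTGGTGCATTCTCCTCATGCCCAAATAGATGTCCGTAGCCGGGGGCGGCACTTGGCTCCCCTATAGGTTTTAACCTCAACATTCGTAGGCCAATTAGTTGC
>synthetic_snoRNA_like_1
ACTTAGCGAACCTATACGGTATAGGTATGCTGGCTACGCGTCTAAGCACATGAGCTTCACGCGGAGTGGAAGGCTTCACACAAGCCGATTTAGCGTACCAAAGTGAATTC
>synthetic_repeat_like_1
AAAGTTTAGAGAGGAGAACGAAATCACCATGGGCGAAAGTTTAGAGAGGAGAACGAAATCACCATGGGCGAAAGTTTAGAGAGGAGAACGAAATCACCATGGGCGAAAGTTTAGAGAGGAGAACGAAATCACCATGGGCGAAAGTTTAGAGAGGAGAACGAAATCACCATGGGCGAAAGTTTAGAGAGGAGAACGAAATCACCATGGGCG
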