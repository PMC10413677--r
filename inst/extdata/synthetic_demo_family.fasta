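>sp1 [species=Synthetic species 1]
CGCACGAGCGGAGTCATCCAGCGGTTACTGTTTATTTAAGGTAGGACCATTACCTTTACC
GGTTCGGCGTTTCTGTTTGTGCATCCTACACCTGCAGGATAAGAGTGGATATAGGGAACA
CCCGAGCTAAAGTTAGTTCTTGGACTGCGTTGTAACTCTATTAAGCTACCACAGGCGTTT
CCTGTAAGGGAGTCGCGTCCCGCGTTCTAGATTGAAATAGGAATCTGTTATATCCCCCTT
GACACCGGTTATGCCGGGGCAGTATTTAAACAGGCATCTTGGGGGAGGACTTTTGCCAAC
TCAGACATAAACATCCACACGTCAGCTTTCCCTTTAGTAGTTTAAGCTGGATGTAACAGA
TTGTGCGAAACCCAAGGAATTAACGAGCGCAAAATACGTC
>sp2 [species=Synthetic species 2]
CGCACGTGCGGTGTCATCCAGCGGTTACTGTGCATAGAAGATAGTACCATGCTCATTACT
AGTTGGGCGTTTCTGTTTGTACATCCTACACATGCCGGATCAGAGCGGATATACCGAAAA
CCCGAGCTAAAGTTAGTTCTTGGCCTGCATTGTTGCTCTATTAAGCTACCACAGTCGTTT
CCTGTAAGTCAGTCGCGTGACCGGTTCTAGATTGAAATAGGAATCTGTTATACCCCCAAC
GACATCGGTTATGCAGGGGCAGTATTTAAACAGGCATCTTGGGGGAGGGCTTTTGCCAAG
TCAGATATAAACATTCACACGTCAGCTTTCCCTTTTGTCGTTTAAGCAGCATGTAACAGA
ATGTGAGAAAGCGATGCAGTTAACGCGCGCAAGATACGGT
>sp3 [species=Synthetic species 3]
CTCACGTGCGGTATCATCCAGCGGTTACTGTTCATTTAAGGTAGTACCATGGTCTTTACC
GGTTGGGTGTTTCTGTTTGTAGATCCTACACTTGCAGGATCAGAGTGGATTTAGCGAACA
CCCGAGCTAAAGTTAGTTCTTGGCTTGCGTGGTTACTCTATTAATCTACAACAGGCGCTT
CCTGTAAGTGAGTCGCGTCACACGATCTAGATTGGCATAGGAATCTGTTATCTCCCCCTT
GATACCTGTTATGCCGGGGCAGTATTTAAACAGGCATCTTGGGGGAGAACTTTTACCAGG
TCAGATAGAAACATTCACGCGTTAGCTTTCCCTTTAGTAGTTTAAGCGGGATGTAACTGA
TTGTGAGAAAGCGAAGCAGTTAACGACCGCAAACTACGGT
>sp4 [species=Synthetic species 4]
CGCACGTGCCGTGTCATCCAGCGGTTACTGTTCATTTAAGGTACTACCATGGTCTAGACC
GGTTGGGCGTTTCTGTTTGTACATCCTACACTTGCATGATCAGAGCGGATATGGCGAACA
CCCGAGCTAAAGTTAGTTCTTGGCCTGCGTTGTTACTCTATTAAGCTACCAGAGGCGTTA
GCTGTAGGTGAGTCGCCTCACCGTTTCTAGATTGAAATAGGAGTCTGTTATATCCCCCTT
CACACCGCTTATGCCGGGGCAGTATTTAAACAGGCATCTTGGGGTAGGACTTGTGCCAAG
TCAGATATACACATTCACACGTCAGCTTTCCCTTTAGTAGTTGAAGCAGGTTCTAACAGA
TTGTTCGAAAGAGAAGCAGTTAACGAGCAAACAATACGGT
>sp5 [species=Synthetic species 5]
CGCACGTGCGGTCTCATCCAGCGGTTACTGTTGATTTAAGGTAGTACTATGGTCTTTACC
GGTGGGGCGTTTCTATTTGCACATCCTACACTTGCAGGATCAGAGCGGATATAGCGAACA
CCCGAGCTAAAGTTAGTTCTTGGCCTGCGTTTTTAGTCTATAAAGCTACCACAGGCGTTT
CCCGTAGGTGTGTGGCGTCACCGGTTCTATATAGAAATAGGAATCTTTTCTATACCCCTT
GACATCGGTTATCCCGGGGCAGTATTTAAACAGGCATCTTGGGGGAGGACTTTTGCCACG
TCAGATAAAAACATTTACACTTCAGCTTTACCTTTAGAAGTTTAAGGAGGATGTCACAGA
TGGTGCGAAAGAGAAGCAGTTTACGAACGCAAAATACGGT
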