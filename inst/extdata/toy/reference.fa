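>chr1
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA
CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC
AACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT
CGTGCATCACAAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAG
TCGTCGGAAAGCAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCC
AGTCCAGGCGAGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATAT
CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACT
CGTGCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACACTG
ATGTCTCCGGGCAGCTCATGACGAGCACCAGACCCGAGAGTTCCTGTTAGTTTTGGTTAGGCACGGAACG
CTATCGAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGT
CGGGACGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGAC
ATCATCGCACGACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGAT
GTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTC
GTATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCC
GGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTGATC
GTGGATTACTAGTTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGC
CTACGTGGAGTCTCTGTGAAATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAG
CCTCGTGCAGCCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTTTCACCGCAGTTACCGTGAAGTG
CCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCCGAACAGTTCGTATTCCCCATGTCTGGACC
GACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGGCCGGATCAAGCAGGATGAGAGG
CACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCATTGATCGTGGATTACTAGTTTTGATG
GCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCTGCAAGCTTTGCCTACGTGGAGTCTCTGTGAA
ATTCAGAGATACGCAGCTAATGGCCCCGCTTAACGGGTGCATCGGCACAGCCTCGTGCAGACTCGTTTCG
CCTTAAAGTCCAACCGTAAAGAAGCGACAGCGACCTAATCCGAGCTTTATCTTTTAAGCGGGCGCGGGGA
TGGAGTCTAAGGCACAGACGGATGCTCATCATATCTCGTAGCATTCATAATGTTGTGAAAAACGGATAGG
CTGGGTCAACAGATATGTGTGGTAGAATTACCGGCAGCTCTTTTGCCGGTGGGTGCCCGGCGACCCGAAA
CTCGGATATGCATGGGGGAGGGCCACCCATTTATGTGCGAGCTGGAAGACGGTTCAGCGGTCCCTCTTTG
GATCGATTCCAAATGACTAACTACGAGACGTGAGGCGTATAGAAACTTAGCGCCGTAGCAGAGGAATCAG
GAGAGGCTGGTAAAACTAAGTGTGAAGTATAAAATGCGGCGCAGTTTGGTAGACTCATAGTATAGGACGC
ATACTCTGAAGTTCGAAGCGGTTCCTTTTTGCTAATTAACCAACAAGCCACGAGAGTTGTCCTCGTGTTT
CGCAGGGTAAATGGACATTTGCGGCCGCCGCTCATGCTCGATATGAATAAGTTCAGTGGGATACCATCGA
TCAGGGAATCCCTAGGCCAGCGGATATCACAATCCCTGTGGCACGGCATGGTGGGCTCCCCTTATCTTAG
GTTTAGTAGCACGCTGATCCGCTCGATGAGCAAAAGACCGACGCAGTCCGCGCTTCATGCAGCTAAGTTA
TTATTAATCTTTCTCCAGGTTGGCTACGCTACCGTTCGGCAAACATATTGCTGCAAGATACTATTAGGTG
GCTGGACTTGGGCTAGTGGCCGACTGCTAAGTATTCCCGTTTCAGTATACTGACACGTGAATCCACCAGG
GAAAACCTTAGTAGCGGCCCGGTATAGCCAGCATAGGGTAGTAAGGGAGGCCATCAACGATCGTGCGGTG
TGGAATCCCAGAGAGGGTAGGAGGCTAAAGCTGTTGAGGGTAGGACTGACAGTGTGAGCGCGAAGGTCGT
GTCTTCGTTA
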