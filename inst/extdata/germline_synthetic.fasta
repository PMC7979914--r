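>IGHV1-46
CAGGTGCAGCTGGTGCAGGCCGAACCATGGCGTGATCTACGCTCATATCGGATTCGGCGCTTAGAGCGTGGCATGCTACGGAACGCAGCCGGCACCTCATGGGGTTTTAGAAGGGTCAGCGTTGTTATTATCATGCACGTGCACGGTCCCATAGTCCTTCTAATTGTTGAGGCCCAAGTGCCAGCGACTTCAACCCGCGACAAAAACCTTCGTCAACCGAAACTCAGGCGCTTGCGATTGCATGTGAGCGTTGCACTCGGTTGGGATTGTGCGCTTGTCTGCAGACTATGT
>IGHV1-3
CAGGTCCAGCTTGTGCAGAAGTTTCATGCTGTCTGTTGGAGCTTCAGCAGACAAGAGGGTGGCCGGGATGATCTACCTCATCTCGGGAGCGTGCCTCACATAGATACGACCTTTTATTCCATGGACAGATCGGAAAATCAGCACGTAGTAGCGGTGGGCGGTAGACGCCATGATCCTTACAACCAGTGCGTCAAAGGAGAGTTAACGCCATTTGGGCCCTTATTCGTCCTTTCGGCGTCACGTGGGATATATTATAAGCACTCGGTGTTGGCGGGACCAGGAGCAAGCTGT
>IGHV1-24
CAGGTCCAGCTGGTACAGCGTGTCGCGGACTTGGCAAATTTCCGTATTGATCCGGGTGATTGCCTTGAAAGTATGCCACGTAACAGAAGCCAGAAAGGGTTTAATAGCTCCCCGTTCTCGCCCTCAGTGGACCCGGTGAGTAGGTATCGAAGCTATCACAAAGGGTCAGTAGCGTGTAAGAGTCGTATAGCGCAAAGGAAATCGACGTCTGGCGTACATGAATACTCCCGTGAGTTACCACCCCATGTCATCAGACTGCTATGTCCATTCATCGAACGTTCCACATTGTGT
>IGHV1-45
CAGATGCAGCTGGTGCAGGTGGTTTCGGTGGATCTGGTGGTTGTCTTGTGGGAGCTTGAAGCAGCGTTAGGCAGCGAGCAGTCCCATTACCAAACGAGCATTAGGGACGGCAACAGTATGTGGACACGGAGAGGGGTAGGACCCTTAGAACCACGACAGTACCCAGCCGAACCTCGACCGTTTGACCTACGGTTTAGCGAGTTCCGCGGGCGCGAACGAAATTGGCCGCTGGGTACGTCAAAACAATCCACAGTGAACGCGGTGCCAGCCCAATTGCCGGTGGGACTATGT
>IGHV2-5
CAGATCACCTTGAAGGAGTTATGGACGCTATGTGCTAGAACACAAGTAATTCTCCGAAAAGACCGGCCTGGTTCCGCTGAAGCCCGCTATAGTGGGCGCATCAGTTGCGCAGTTCCATGGCTTGGCGCCAGTCGGCTCCATATGACGACCCCTGGGTTAACTTCACGATACCGGGATTCGCTACACTTATTTTTAGCAATATTATACCTTAAGGGGGATTCGGCTCTGGCTACAGTACAATGTAAGGCATCCACCGTTAAGAGCACAGGCTTGCAGAAATCGCGTCAATGT
>IGHV2-26
CAGGTCACCTTGAAGGAGGCTCAGTTTGTGAATCACGCATGCAGTACGCAGGTGTGGCCCCCTAGTTTATGTTTGAGTGACGGCAGGTGTTGCAATGATCCCGGTCGTAGCACTCGGAGTGCACGCGAGTTGTTACGTACGACGTTTCGCCTAGCTCCACAACAACTATATTTTCAGTCTTCTACGAATGTAGGTGTTGGTCGGAGGACAATCAATTCTAAGGTGACGGTAGGTTACGGATTCATGAAAAAGAATTCCCATTTCTACCGGACCCCCCATCCCTTGTGTTGT
>IGHV3-7
GAAGTGCAGCTGGTGGAGGTCGAGACACTACGTTACGCGTGCCGAAGCCTCCTGAATAGCGGAGCGAGAGTGATGCATGGTGAGTCATTCTTCCGCATTTGGCTGCTCTGTTGTCAACAAAACAGCTTATGGCGAGTTACGAGCATGTCAAATGTGAAGCTGATAACGTTCACAGAGTTATTCACCTTCGTGTCCGGCTTGTTACCAATACCTGAGACGAGACCTGAGATCAGGACATTGTCTCGAGCCTTCCGTGAACAAAGTAGACGTCCTCGGTTTCAAAGAGCTTGT
>IGHV3-30
CAGGTGCAGCTGGTGGAGAATCATGCAGACACAACTATGGACGGTGACGCAAAAACAAGGAGCCACGTAAAACCTACGCATTACGTCCGATTGCCTATTATAGGAACCATCCTCTGCGACTCAGGTTTGTTCACAGCTAGACCATCACACGCTGAGGTCCTGCCTGTTCGGGAACCGAATAAGATTTCGTGTGGAATAGTCATTTCGGCTATAAGTAGACTTTTCCTGGGTGCACTCATCAACAAATTAGTATGTCTCACTCTTGAGGTCCGATTGTTCTTGCTCATATGT
>IGHV3-23
GAGGTGCAGCTGTTGGAGTGCCATAACCGAGCGAAAGCCCCTGAGTCGACGTGTCCGCTACACCGGCAATCTTATGATTCATTCACCATATTGAGAGCAATAGTCAACAAAAAACGGCCGTTACCACAACACGGTGGATTGGCTATGACAGACGTCTCAGCAGGACATAGGCGCGCTGTTCTGTCGCATATCGTTTCAAGACGGGCATCGATGATGGGGACATCGCCCAGGCTAACGGGACCTCTCTTGGATGGCGCCGTATATAATGCTTTGATACGTCGTAACAAATGT
>IGHV4-4
CAGGTGCAGCTGCAGGAGGCGGATCTATCGCCTGACTTACGAGTCCTGGCCTTCAGACAATCGAGGATAGCGGACCCTCGGGAGCGGCTGGCCCTCCCTTTTGAGTGCATAATAGTGCTCCCAACTCCAAACGGAATGCTTGTGCTACTGCTCAGCTTGTGGCGCTCCCCGCCGTGCTCCTCGCCGAAGAGACATGTGGTGAATCTGTCATATTGCGAAAAGTTCGTATTGTCCCTTTCCAGAACGGTTCTGTATCTCGGCTCGGTGCTCGATGCGTTCAAACTGTGTTGT
>IGHV5-51
GAAGTGCAGCTGGTGCAGTCGGTTGCGCAGACCGACATGAATACCAATTCCAGGAAGGCTATAGACAAACTACATGCCCATGTACGACTTTACGGTATAGCAAACCGACCCGCCTCCCAGCTGATTTTCAACAATACAGTTAGTTGTTGCTACCTACAGGGTCGTACATCGTGTTATAGACAGGGGCCCGATCCTCTGCTCGTTGGCAGGGGCGTCACTTGGAGCCGATCATCTGTGCTGAGGCGTATAGGACCGAAGCGTATGCCAAGGACTCGGTTCGTCGAGGACTGT
>IGHV6-1
CAGGTACAGCTGCAGCAGGCAGAACCTGTGGAAGGACACTTAGCTGGGAGCCTTTGCGCCCTTCGAATTGTGTTAGCCTGTCGAGAGGCGGACGTTCTCAATCGCTCGGCCACGTATATGCGGATCTTCCGTTCCCTTATAACACCTGGTCCATGGCGGCGTGAGTACGTTGTCGTTATAACGAAGAGCACGGGTCAAGAGTCTTTGTCCCTGGTCAGCGTAGAAACGTTAGCTACTTGTACGCGCTTCAAAGAACTCCAATCGGTTCAGGTCATGAGCAGGGGCTCATGT
>IGHJ1
TGGGAATGGAGACTGGAGTTGGGCAATCCACGAGGGAAC
>IGHJ2
GTCCTCTGGTCATTGTTATACGCTGGCTGTAAATTATTG
>IGHJ3
TTTCGGTGGCTATCTAGAATAATGATACTGGTTATGAGT
>IGHJ4
AAGTATTGGTACGGATCGAAACCTGTTCGCGGCGCGAAT
>IGHJ5
GACTTCTGGGCACGTAGCCATTCACTAGTAGGGGCTTCT
>IGHJ6
GTACAGTGGCGTATTTTCTCCCTCTTTGCACTATCATGC
>IGKV1-39
GACATCCAGATGACCCAGTGTAAGGAATACTGCCCGCGCGACAGAAGTAATGTCTTTTTCAGGACGACCGGCGCACGAGAATGCTACTGCCAAAGGGGAGCAACGTTAGGCCGGATCCAGGCGAGTGGTCCCAGTGTGCTTCCATTACACTTCATCACTAGAGGTCAATCACGGGTCAGTAGCGGAAAGCGGCGGGGAGAACTCTACGTACATCCACGCGAGCCGTTAAGATTAGAGCTTGTAATAAGAACTACCCGTGTAAAAATCATACCCCGCCCCTTGTTAACTTGT
>IGKV1-9
GACATCCAGTTGACCCAGCGTATACCGGTTACCGAGCTGCTGTCCGAAGCTGCATATCTGCCTCGTATGCCACTTTGTTACTGTGATGTTGTGGCCACGTGGAGCGTTATAATAACGCCGGGGTTGGAGATTTTACATCCGCTCTTAGGTCTGTACTGTCTACTGCGGCCCACAATGCTTGGACTCAACAATACACTACAAATGGGTTGTGGATGCCCAGGTAGTCCGCATCGGCTTTCGCCAGGAATGAGGATGAACATCTGCAGCTCGGGCTCAACAGGATCTACGTGT
>IGKV1-5
GCCATCCAGATGACCCAGCACGTTACAATGAGACTCTTACTTGTACCCGCCGACAGAATACCTTGCCTCGGAGGCCCTACCTATAAACAAACGAGCGTACCATTTGCTGCCCGAAGGATGTTAGCCGATGACCGGATGAATATTTTTTGTGTGACCCGGTGGTGTGCTGTACAGCACGCGGACATAGTGCGTACCTTAGAGTCCCCGAGCATACGCTTGGCATTGGGTGCGTTGATGAGGAGTCCCAGGGCAATCAAAGTCGACTTCGATAAACTGCTATGTGGGCTTTGT
>IGKV1D-8
GTCATCTGGATGACCCAGGGATTACCCGCGGGTACTAAGTATTATTGGAGCCAGTGCGTCATTAGACGCCTGTATCGTCAACTCAATGGAGGATGGATTCTAGACGTTTTGTGCACGCCCTACCACGTATCGGTGAAGACCGTGTTTTTCCACTACGGCCACCACAGTGCGATGTTCTACCCGCGGCGACACCTAATAGTCGCCATTTCTTTCGGAAGGTGTCGTAATCCGAATGGACGATTTTCGTCTGTCAGTTACCTTCTTGAACCTAGCCACCGGTTCCGGTTTTGT
>IGKV3-20
GAAATTGTGTTGACGCAGAGCGCCCTAATGTCCATGGTTGATTATGAAAAAGGAGACAGGACTGCCGTGAGCTTACACTGCGTTCATTACTGGCATCGCGTCGATGGTATTATTAACAGCGTGGGTTTACTACCGCCCTGTGGGGGTGGATCGAACCATCACATATATAGAGAACCCCGCTTGCTATGCATAGGTTGCCGATGCACCCCGTGTGACGGGAGTAATTGCACAAAGAATCTCCAAAGGTCAGCTAGGCATTGGATGGCGATAGCTGGAAGCCAGTCCGTATGT
>IGKV3-11
GAAATTGTGTTGACACAGCTGAACTTAGTGTTCGGCTACTGTACGTCACATGTATTGCGAGGCCGAAAAAGTGCCTCCTCACAGCGATGGAGCTGCGACTCTCAAAAGTATATAGATCCGCGACTGCGTAGGAGGCTATGCCTAACTTCTTGCGATCGGATAGTCAGAAGTATTTTGTTTCAACTTATTGAATGCTGCGAATACTTAGCCTTCAGCGCGACCTACTCTAAAGACTACCCAGGGATCCCACCCCGCGCCCCTGACCCGACCAGTAGTGATGACCATCCGTGT
>IGKJ1
ATCTACTTCGGACCGCTGCAACTGTACACGATCGACAAA
>IGKJ2
TCCGCCTTCCCTAACCGGGGTTCTTTAATGGAAAGAGCC
>IGKJ3
AGAGCCTTCAATGGATGTAACGACCTTATAAATCCCGTC
>IGKJ4
AACAAATTCCTCCTGGTGCACGTCCCTGCTGTGGGATCA
>IGKJ5
AAACGGTTCAGGTATTTCAGAGTGTCTTTGGTGTTCGCG
>IGLV1-47
GAAATAGTGATGACGCAGGTGGGGAATTATTATCTAAATGACAGATCAATGACCGTCCTAGGCGACCTCCTTTCCACCAAGCAGACCGGCAGGGCTACCATATGGAAAGTGAATACCATTAGGAATCTTCGCCATTCTTTCATGGGTTGCGAAACCCTCATGAATTGGGTACATGGAAATGGGATCGCCCGGCCCACATCCGCCTGGAGTTACGTCATTAGCAGCGAAGCCTCCGGTTTAAGTGTTACGAGGCGCAACGTGCCTTACGGCTTATTCAAAATGTATCCGTGT
>IGLV1-40
CAGTCTGTGCTGACTCAGCGGCTCCCTTCTGCCTCCGGCCTTGTCACATTTTGCCCGCGCTCCCTCTGGACACTATCGTTGCCATTCCAGCACCCCAAACCTTACTACGAACGGTTACGGAGAGCGCGTCTTTTGTCTCCGCCTCTTGACCAGCTCAGACGATGTGCTCCCAAGACTCTCGCAATCGCCGAATATTCACCGGGAGAACTGCGGCGCAATAACTTGGTACTACGAGCAGTCAAAGGATCAGGACTCTCCAGCCCGCCACCGCCAATAGAAAGAGATTTTTGT
>IGLV2-14
CAGTCTGTGCTGACGCAGGCGTCGCCGACCCCGTCTGAACAGGGTGAGGCAGCGGAATGTAGCTCCAGGTCCGTGCTTGGTCTTTCCCGCACGAAGTATGACAAGACAAGTGCTGTGATTTTTAGGGCCCCCAGAAATAGAATCGTCCTGATTAAGATTTCTCCCGGTCACGCATGGCTCTTCATATTCGGACGCATCATAGGTATATTTATGCTTCAGTGGTCCATAGGTGGGTCGATGCTAGAAGATATTTCCACGTCCACTAATTCGTGGAGAGCCGGGTTACTGTGT
>IGLV3-21
CAGTCTGCCCTGACTCAGCGAACAAATCCTGATCAACTACCTGGGGCTCAATGGTTCGGCTTCGGTTCAATATGCAGCCTCTATGCGATTGCCGCAAGCGGATTTAGCCCGGCTGGAAGTTCATGTGTCCCTGCGTATCTATTCGTAGACGCCGCCGCGAGTTCTCGCTCCGTTAGCAAAATCGTCACCAGATTGTCACGATTTATGCCTGATATTTCAGTTTCCCGCGACGTTAAGGGGCCAGCCCCCAAACGAGAGCATCCAATAAATAGATCGCTCGTTATTACTTGT
>IGLJ1
GTATATTTCTACGACCATCGTTACTATAGCGGTGGGGGA
>IGLJ2
CACACTTTCTTTGAACTTTCTTGTGTATTTTACCTACTG
>IGLJ3
CATGGATTCCACTCTACCAGATTCTCCTTCCATCGAAGC
>IGLJ7
TCAGGATTCAGGAAGAGACATGCCTTCTTGTTAAGAAAC
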