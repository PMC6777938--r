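>SmarSuHex2-3_WT role=wild_type pair=SmarSuHex2-3
CGCTGGATCCGCGGCCAGTATGACTACCCGCCGCCGTTAGCCAGCACATACAGCCGCGAGGCCGACCTGTGGAACGTGAACCTGGCCACCTACAGCAGCGCACCGACCACATGCACCGGTGCAACCCCGGCACCTAGCGTTACCGGTTTCTACGCCCAGGCCACCGGCAGCAACAGCGTTAGCCCGAGTAGCGTGAGCCTGACCACCCTGACCCCTCACTTCGCCGACAACCACCCGGTGGACCTGAGCAACAGCCATCGCGGTGAAGGCGGCCACCTGGATCTGGTGCGCTTCCAGAGCGACCGCGTGGATGCCTACAAGCACGCCAACGGCCTGAGCGTGCATATCCCGGACCACCACGCATAACTGGTACCATGG
>SmarSuHex2-3_mut role=mutant pair=SmarSuHex2-3
CGCTGGATCCGCGGCCAGTATGACTACCCGCCGCCGTTAGCCAGCACATACAGCCGCGAGGCCGACCTGTGGAACGTGAACCTGGCCACCTACAGCAGCGCACCGACCACATGCACCGGTGCAACCCCGGCACCTAGCGTTACCGGTTTCTACGCCCAGGCCACCGGCAGCAACAGCGTTAGCCCGAGTAGCGTGAGCCTGACCACCCTGACCCCTCACTTCGCCGACAACCACgCCGcaGcTGcGgCTAACAGCCATCGCGGTGAAGGCGGCCACCTGGATCTGGTGCGCTTCCAGAGCGACCGCGTGGATGCCTACAAGCACGCCAACGGCCTGAGCGTGCATATCCCGGACCACCACGCATAACTGGTACCATGG
>DmelHairless192-389_WT role=wild_type pair=DmelHairless192-389 range=192-389
CGATGGATCCGAGCAGTGGTTGCAGCAGCAGCTGGCACTGCCAAAATTGGTAAAGGCAGCAACAGCGGTGGCAGTTTTGATATGGGCCGCACACCGATCAGCACCCACGGCAACAATAGTTGGGGTGGCTATGGCGGCCGTTTACAGTTCTTTAAAGATGGCAAGTTTATTTTAGAACTGGCCCGCAGCAAAGATGGCGATAAAAGCGGCTGGGTGAGTGTGACCCGCAAAACCTTTCGCCCGCCGAGTGCAGCAACCAGCGCAACCGTGACCCCTACCAGTGCCGTGACCACCGCCTACCCGAAGAATGAAAACAGCACCTCTTTAAGCTTCAGCGACGACAATAGCAGCATTCAGAGCAGCCCGTGGCAGCGTGATCAGCCGTGGAAACAGAGTCGTCCGCGCCGTGGCATCAGCAAAGAACTGTCTTTATTTTTCCACCGCCCGCGCAATAGTACACTGGGTCGTGCAGCCTTACGTACCGCAGCCCGCAAACGTCGTCGTCCGCATGAACCGCTGACCACCAGCGAAGATCAGCAGCCGATCTTTGCCACCGCAATCAAAGCCGAGAACGGTGATGATACTTTAAAAGCCGAAGCAGCCGAATAACTGGTACCATGG
>DmelHairless192-389_5Amut role=mutant pair=DmelHairless192-389 range=192-389
CGATGGATCCGAGCCGTTGTGGCAGCAGCAGCTGGCACTGCCAAAATCGGCAAAGGCAGCAATAGCGGTGGTAGCTTTGACATGGGCCGCACCCCGATTAGCACCCATGGCAACAACAGCTGGGGTGGTTATGGTGGTCGTGCCCAAGCTTTTAAAGACGGCAAGTTCATCGCCGAAGCCGCACGCAGCAAAGATGGCGACAAAAGCGGTGCCGTGAGCGTGACCCGCAAAACCTTTCGTCCGCCGAGTGCAGCAACCAGCGCAACCGTTACCCCGACCAGCGCAGTTACCACCGCCTACCCGAAAAACGAAAACAGCACCTCTTTAAGCTTTAGCGACGACAACAGCAGCATTCAGAGCAGCCCGTGGCAGCGCGATCAGCCGTGGAAACAGAGCCGTCCTCGTCGCGGCATCAGCAAAGAGCTGTCTTTATTCTTTCATCGCCCGCGCAATAGCACTTTAGGTCGTGCAGCACTGCGCACAGCAGCACGTAAACGTCGTCGCCCGCATGAACCGCTGACCACCAGCGAAGACCAGCAGCCGATTTTTGCCACCGCAATCAAAGCCGAGAACGGCGATGATACTTTAAAAGCAGAAGCAGCCGAATAACTGGTACCATGG
>PtepSCAP233-432_WT role=wild_type pair=PtepSCAP233-432 range=233-432
CGATGGATCCGAACCGTGAATACCGAAGATCCGCCGAAGGATAGCATCAACTTTCTGGACCACAGCCGCGTGACCGATCCGTGTAGTGCCGCAAGCGAAACCAGCCTGCCGCAGGATGTGCCGGCAACAAGCACCGTGGGCAGCCTGAAATTTTTTCTGGGCGGTCGCCTGGTGCTGAAATTAAACGCCCAGCAGGATGGCGGCAGCGGCAATAAATGCCAGTGGGTGCAGAGCAACGATCTGCCGAAACATAGCAACCATAACAAAAAAGATAAACATAAGAAAAAATTTGCACCGTATAGCTATAGCAGCAGCGGCACTCAGAAACCGCTGAAGAAAGGCGACGATACCAGTGCCGTGCCGGACTGTGATCCGAGCGGCATCAAAAAGCCGCGCCTGAAAGAGTACGAGACCAGCGAGAATAGCGCCCTGGGTCTGCTGCTGTGCAGCAGCAGTTGGACCCCGCCGGTTGCAGATGGTCAGGAGAGCATTGACGTGGACGATACCAGCAGCAAAACCAGCGAGGGCTATATTAGCCCGATCCTGAGCAACAATAGCCGCACCAGCAAAATCGACACCATCAAGCACGATTTTGCCAGCAACCCGAACACCTAACTGGTACCATGG
>PtepSCAP233-432_5Amut role=mutant pair=PtepSCAP233-432 range=233-432
CGATGGATCCGAACCGTGAACACCGAAGACCCGCCGAAAGATAGCATCAACTTTTTAGACCATAGCCGCGTGACAGACCCGTGCAGTGCCGCAAGTGAAACCTCTTTACCGCAAGATGTGCCGGCAACCAGCACCGTGGGTAGCGCCAAAGCCTTTCTGGGCGGTCGTCTGGTGGCCAAAGCCAATGCCCAGCAAGATGGTGGTAGTGGTAACAAATGCCAAGCTGTGCAGAGCAACGATCTGCCGAAACACAGCAATCACAATAAGAAAGACAAACACAAGAAAAAATTTGCCCCGTATAGCTATAGCAGCAGCGGCACCCAGAAACCGCTGAAAAAAGGCGATGACACCAGCGCAGTGCCGGATTGCGATCCGAGCGGCATTAAGAAACCGCGTTTAAAGGAGTACGAGACCAGCGAAAACAGTGCTTTAGGTTTACTGCTGTGCAGCAGCAGTTGGACACCGCCGGTGGCCGATGGTCAAGAAAGTATCGATGTGGACGACACCAGCAGCAAAACCAGCGAAGGCTACATCAGCCCGATTCTGAGCAACAATAGCCGCACCAGCAAAATTGATACCATTAAACATGATTTTGCAAGCAATCCGAATACCTAACTGGTACCATGG
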