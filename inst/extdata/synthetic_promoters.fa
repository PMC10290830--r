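>prom_001
ATTCAAATTTTGCTTTCATCCTACAAATATAACCTTTAGCTTCACCTTCAGACCTTAACTCAACCTTTCCCAGGCAAACC
GCTCCACAAATCCCCAACTG
>prom_002
ATATCCTCGTTAAGCGCGGGGATGCGGCCGCATGTTTCGCGGTTCATTCAGTTGTCTATAATACCGGGATTGGACTTCTT
AGGTCGTGCACAGAGAAGTT
>prom_003
ACGCTAATACATTTACGAACGAGTTATAAGTGTATAGGGCTAGTCTTGAAGTTGTACCAAAAAATGAATTAGCCAACATG
TCTGTATACCGAACAAGAAA
>prom_004
AAGTGTACATTCGCCCGCTGCATCAAAGTTAAATCTCTGACGTAACCTCACTCACAACCAACCTTTATTTTATCCTAGAG
TATCAGCAACGTTCGAATGA
>prom_005
GACACTAAACTGGGAAAATACGATTACATCGTTCTCCCATCTTCTCCTCAGTTAAAGCCCCAATATACCAGCGAGCTTAG
GGTGCATTCAGAATGTTTTC
>prom_006
GGTAGAAGCACAACCAGAATCGTGTTGGAGATATTAATGTGTAGGCGTTATTTAGGTATAATTTTGCGTAGTTCATAGAG
TCCTTAAAATACATAGCTAT
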