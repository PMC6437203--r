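>INNER_001
GTCTTCGCGATGAAGCCCGCAGTTCCAACTCCTCAGATTTGCATACACAAGAAGGTTTGG
>INNER_002
CTGACACTGTATCCTGAACACCGGCAAGTGTAGACCATAATCTGCCCTATCATCCAATCT
>INNER_003
CTGACACTGTATCCTGAACACCGGCAAGTGTAGACCATAATCTGCCCTATCATCCAATCT
>INNER_004
GTCTTCGCGATGAAGCCCGCAGTTCCAACTCCTCAGATTTGCATACACAAGAAGGTTTGG
>INNER_005
GGGCTCGTGCACTCCAACGGTGGACAGATACAATATCGAAACTATTTCTAAAGACATAGA
>INNER_006
ATACTAGTAAGCAGTCCGAAACGTCTCGCAGAAGGTCCCCAATGAGAATTGAGTAGTCGT
>INNER_007
ATCCGGAAGATACAGTACTCCGACTATGCTTGACAATTCTACTAGCTCCACTAATAGAGG
>INNER_008
CTGACACTGTATCCTGAACACCGGCAAGTGTAGACCATAATCTGCCCTATCATCCAATCT
>INNER_009
GGGCTCGTGCACTCCAACGGTGGACAGATACAATATCGAAACTATTTCTAAAGACATAGA
>INNER_010
GTCTTCGCGATGAAGCCCGCAGTTCCAACTCCTCAGATTTGCATACACAAGAAGGTTTGG
>INNER_011
GTCTTCGCGATGAAGCCCGCAGTTCCAACTCCTCAGATTTGCATACACAAGAAGGTTTGG
>INNER_012
AGCACACGCAATGTAATCAGCGCTCTTGGCCCCATCTACGCCTAATTCACGATGACTCCA
>OUTER_013
ATACTAGTAAGCAGTCCGAAACGTCTCGCAGAAGGTCCCCAATGAGAATTGAGTAGTCGT
>OUTER_014
ATCCGGAAGATACAGTACTCCGACTATGCTTGACAATTCTACTAGCTCCACTAATAGAGG
>OUTER_015
CTGACACTGTATCCTGAACACCGGCAAGTGTAGACCATAATCTGCCCTATCATCCAATCT
>OUTER_016
GAATTTTCGATCTCGGCAGGGTTTTAGGGCCTCTCGCCCGTCTATGCGAGAATTCGCTTG
>OUTER_017
GGGCTCGTGCACTCCAACGGTGGACAGATACAATATCGAAACTATTTCTAAAGACATAGA
>OUTER_018
CTGACACTGTATCCTGAACACCGGCAAGTGTAGACCATAATCTGCCCTATCATCCAATCT
>OUTER_019
ATCCGGAAGATACAGTACTCCGACTATGCTTGACAATTCTACTAGCTCCACTAATAGAGG
>OUTER_020
ATCCGGAAGATACAGTACTCCGACTATGCTTGACAATTCTACTAGCTCCACTAATAGAGG
>OUTER_021
GGGCTCGTGCACTCCAACGGTGGACAGATACAATATCGAAACTATTTCTAAAGACATAGA
>OUTER_022
GAATTTTCGATCTCGGCAGGGTTTTAGGGCCTCTCGCCCGTCTATGCGAGAATTCGCTTG
>OUTER_023
GGGCTCGTGCACTCCAACGGTGGACAGATACAATATCGAAACTATTTCTAAAGACATAGA
>OUTER_024
TGGTCGTAATACGCCTACATAACGCACAGTATTCATTACGAGCCGCACGTGTTGCCTGGA
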