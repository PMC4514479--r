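>target_probe_1|odd
ATGGAAACCAGAATTCGCGC
>target_probe_2|even
CGAGTAACAAACTGCCGCAG
>target_probe_3|odd
AAAACCAACTCTTCACCAGG
>target_probe_4|even
CATGGAGAGACCAAACTGCT
>target_probe_5|odd
TGAGCAAAGGGAAGCTGTCA
>target_probe_6|even
ACATAGTTCTAGCAGATGCT
>target_probe_7|odd
AGGCCAGAAAATGTCCAGAC
>target_probe_8|even
AACACATCCCTTTATCTTCT
>target_probe_9|odd
ATCCACAGCAAAAAGGCTGG
>target_probe_10|even
TCTTCAGCAATGGATGGTGA
>target_probe_11|odd
TAGTGTCAGGTGTGTTTGAC
>target_probe_12|even
GTGGAGAAGGGTGAGAAGAC
>target_probe_13|odd
TAGGTATTTTTCAGTTCTGT
>target_probe_14|even
AATGCTAAAAGCAGGGGATC
>target_probe_15|odd
AGTTTAGAGAAGTATGCCAT
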