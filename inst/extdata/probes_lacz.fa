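>lacz_probe_1|control
ATTAAGTTGGGTAACGCCAG
>lacz_probe_2|control
AATAATTCGCGTCTGGCCTT
>lacz_probe_3|control
ATCTTCCAGATAACTGCCGT
>lacz_probe_4|control
AACTGTTACCCGTAGGTAGT
>lacz_probe_5|control
ACCATTTTCAATCCGCACCT
>lacz_probe_6|control
TGGTTCGGATAATGCGAACA
>lacz_probe_7|control
ATTTGATCCAGCGATACAGC
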