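>O1
AATTGTGAGCGGATAACAATT
>O2
AAATGTGAGCGAGTAACAACC
>O3
GGCAGTGAGCGCAACGCAATT
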