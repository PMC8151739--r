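diameter_mm,k
6,0.541
9,0.302
12,0.191
15,0.152
18,0.122
21,0.113
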