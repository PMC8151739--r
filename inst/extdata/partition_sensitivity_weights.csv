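partition,weight
A1,0.146
A2,0.092
A3,0.082
B1,0.151
B2,0.182
B3,0.213
B4,0.134
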