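partition,k_calculated,k_actual,error_pct
A1,0.13,0.14,7
A2,0.11,0.10,9
A3,0.15,0.16,7
B1,0.33,0.34,3
B2,0.26,0.24,11
B3,0.12,0.11,8
B4,0.14,0.15,7
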