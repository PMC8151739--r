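partition,Pv,Pm,Gm,Gv
A1,1.94,7.04,2.16,0.21
A2,3.23,8.72,3.57,0.29
A3,1.24,4.68,1.77,0.22
B1,2.89,7.14,1.92,0.23
B2,1.86,5.19,1.71,0.21
B3,3.04,8.26,2.36,0.36
B4,1.47,5.12,1.93,0.29
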