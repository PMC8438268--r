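hu,spr
-1000,0.001
-325,0.7
-105,0.95
-5,1.01
45,1.04
175,1.1
265,1.13
715,1.31
1585,1.66
2000,1.827
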