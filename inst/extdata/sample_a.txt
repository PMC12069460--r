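# 4 sequences of 4 SNPs; 758 minimal genealogies of length 9
0011
1011
1000
1100
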