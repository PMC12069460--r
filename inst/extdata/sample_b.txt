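# 4 sequences of 4 SNPs; 414 minimal genealogies of length 9
0101
1000
1010
1101
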