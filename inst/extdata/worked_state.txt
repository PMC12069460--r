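# worked action-inventory state: 2 mutations + 12 recombinations
0100
1000
1010
0011
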