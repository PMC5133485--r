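1 50 300 GENE1
1 200 400 GENE2
2 4000 6000 GENE3
3 1 1000 GENE4
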