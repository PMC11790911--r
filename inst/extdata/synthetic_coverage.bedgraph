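geneA	0	40	3
geneA	40	90	7
geneA	90	100	0
geneB	0	30	12
geneB	30	100	9
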