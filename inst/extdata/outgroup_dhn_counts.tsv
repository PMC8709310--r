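species	n_genes
Aegilops tauschii	9
Hordeum vulgare	8
Zea mays	7
Oryza sativa	6
Sorghum bicolor	5
Triticum aestivum	19
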