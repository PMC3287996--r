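factor	wt	mut
Sp1	CCGCCCCCGCC	AAGAACAAGAA
Sp1	GGGGCGGGGG	GGTTCTTTGG
Sp1	CCCCGCCCCC	CCAAGAAACC
Sp1	CCCCGCCCCG	CCAAGAAACG
CREB	GGTTGTCGTCATGG	GGTCGACGTCATGG
HNF-1	TGGAGTTAATCATCTACTCTG	TGGAGTAAGTCTGCAACCAGG
NF-Y	GGCCCCATTGGCTGCCT	GGCCCCTCCAGCTG
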