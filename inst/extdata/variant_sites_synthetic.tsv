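site	taxon	accession	position	residue
bLG_DN1	Bos taurus	SYNLACB1	15	D
bLG_DN1	Ovis aries	SYNLACB2	15	N
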