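rule_id	smarts	note
pains_ene_rhodanine	O=C1NC(=S)SC1=[CX3]	rhodanine with exocyclic alkene
pains_quinone_a	O=C1C=CC(=O)C=C1	para-quinone
pains_catechol	[OX2H]c1c([OX2H])cccc1	ortho-dihydroxybenzene
pains_azo_aryl	cN=Nc	aryl azo dye core
pains_hzone_phenol	[OX2H]c1ccc(cc1)C=NN	hydroxyphenyl hydrazone
pains_ene_one_ene	C=CC(=O)C=C	divinyl ketone cross-conjugation
pains_alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=[CX3]	alkylidene barbiturate
pains_mannich_b	[OX2H]c1ccccc1CN(C)C	phenolic Mannich base
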