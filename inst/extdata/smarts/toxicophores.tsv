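rule_id	smarts	note
tox_nitro_arom_charged	c[N+](=O)[O-]	aromatic nitro (charge-separated form)
tox_nitro_arom_neutral	c[NX3](=O)=O	aromatic nitro (pentavalent form)
tox_acyl_halide	C(=O)[F,Cl,Br,I]	acyl halide
tox_aldehyde	[CX3H1](=O)[#6]	aliphatic/aromatic aldehyde
tox_epoxide	C1OC1	epoxide
tox_aziridine	C1NC1	aziridine
tox_hydrazine	[NX3;H1,H2][NX3;H1,H2]	hydrazine
tox_azide	N=[N+]=[N-]	azide
tox_isocyanate	N=C=O	isocyanate
tox_thiol	[SX2H]	free thiol
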