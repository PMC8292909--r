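rule_id	smarts	note
mcr_polyene	C=CC=CC=C	extended acyclic polyene
mcr_quaternary_n	[N+X4]	permanently charged quaternary nitrogen
mcr_disulfide	[SX2][SX2]	disulfide
mcr_peroxide	[OX2][OX2]	peroxide
mcr_vinyl_ketone	[CH2]=[CH][CX3]=O	Michael-acceptor vinyl ketone
mcr_acrylonitrile	C=CC#N	Michael-acceptor acrylonitrile
mcr_alkyl_halide_reactive	[CH2X4][Br,I]	reactive primary alkyl bromide/iodide
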