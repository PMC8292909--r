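gene,protein_name,log2fc
SERPINB8,serpin B8,0.72
FUCA1,tissue alpha-L-fucosidase,0.64
NMI,N-myc-interactor,0.60
CPVL,probable serine carboxypeptidase CPVL,0.56
GSTM1,glutathione S-transferase Mu 1,0.52
RCHY1,RING finger and CHY zinc finger domain-containing protein 1,0.51
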