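gene,protein_name,log2fc
SRPK1,SRSF protein kinase 1,-0.5
CDCA3,cell division cycle-associated protein 3,-0.52
CDC20,cell division cycle protein 20 homolog,-0.52
TYMS,thymidylate synthase,-0.52
PEG3,paternally-expressed gene 3 protein,-0.53
TCF3,transcription factor E2-alpha,-0.55
FDX1,"adrenodoxin, mitochondrial",-0.56
FAM49A,CYFIP-related Rac1 interactor A,-0.56
FLI1,Friend leukemia integration 1 transcription factor,-0.57
ATAD2,ATPase family AAA domain-containing protein 2,-0.57
PSRC1,proline/serine-rich coiled-coil protein 1,-0.59
PBX1,pre-B-cell leukemia transcription factor 1,-0.6
PAPOLA,poly(A) polymerase alpha,-0.61
NRG1,"pro-neuregulin-1, membrane-bound isoform",-0.62
NKX2.2,homeobox protein Nkx-2.2,-0.67
EPHB3,ephrin type-B receptor 3,-0.68
PCCA,"propionyl-CoA carboxylase alpha chain, mitochondrial",-0.73
SALL2,sal-like protein 2,-0.7
OLFM1,noelin,-0.76
DAPK2,death-associated protein kinase 2,-0.7
RBBP8,DNA endonuclease RBBP8,-0.79
FZD1,frizzled-1,-0.8
CENPM,centromere protein M,-0.81
RCC1,regulator of chromosome condensation,-0.84
DEPDC1,DEP domain-containing protein 1A,-0.86
LDB2,LIM domain-binding protein 2,-0.88
PAXIP1,PAX-interacting protein 1,-1.08
MSC,musculin,-1.09
NPY1R,neuropeptide Y receptor type 1,-1.1
EFNB1,ephrin-B1,-1.1
HIPK1,homeodomain-interacting protein kinase 1,-1.11
IVNS1ABP,influenza virus NS1A-binding protein,-1.24
GAS1,growth arrest-specific protein 1,-1.56
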