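# Stand-in reference pool of typical whisky/food volatiles (esters, fatty
# acids, phenols, terpenoids, lactones, aldehydes, alcohols, furanones).
# Curated for this package; NOT the literature reference list used in the
# original study, which is not redistributable here.
CCO	ethanol
CC(C)CO	isobutanol
CCC(C)CO	2-methylbutanol
CC(C)CCO	isoamyl_alcohol
CCCCCCO	hexanol
CCCCCCCCO	octanol
OCC1=CC=CO1	furfuryl_alcohol
CC(O)C1=CC=CO1	1-(2-furyl)ethanol
CCOC(C)=O	ethyl_acetate
CCCCCC(=O)OCC	ethyl_hexanoate
CCCCCCCC(=O)OCC	ethyl_octanoate
CCCCCCCCCC(=O)OCC	ethyl_decanoate
CCCCCCCCCCCC(=O)OCC	ethyl_dodecanoate
CC(C)CCOC(C)=O	isoamyl_acetate
CCCCCCCC(=O)OC	methyl_octanoate
CCCCCCCCCC(=O)OC	methyl_decanoate
CCOC(=O)CC(C)C	ethyl_isovalerate
CCOC(=O)C(C)C	ethyl_isobutyrate
CCOC(=O)CCC(=O)OCC	diethyl_succinate
OC(=O)C	acetic_acid
CCCC(O)=O	butanoic_acid
CC(C)CC(O)=O	isovaleric_acid
CCCCCC(O)=O	hexanoic_acid
CCCCCCC(O)=O	heptanoic_acid
CCCCCCCC(O)=O	octanoic_acid
CCCCCCCCCC(O)=O	decanoic_acid
CCCCCCCCCCCC(O)=O	dodecanoic_acid
CC=O	acetaldehyde
CCCCCC=O	hexanal
CCCCCCCC=O	octanal
CCCCCCCCC=O	nonanal
O=CC1=CC=CO1	furfural
CC(=O)C1=CC=CO1	2-acetylfuran
O=CC1=CC=C(CO)O1	hmf
COC1=CC=CC=C1O	guaiacol
COC1=CC(C)=CC=C1O	4-methylguaiacol
COC1=CC(CC=C)=CC=C1O	eugenol
COC1=CC(C=O)=CC=C1O	vanillin
CC(=O)C1=CC=C(O)C(OC)=C1	acetovanillone
OC1=CC=CC=C1	phenol
CC1=CC=C(O)C=C1	p-cresol
CCC1=CC=C(O)C=C1	4-ethylphenol
CC1=CC=CC=C1O	o-cresol
CC(C)=CCCC(C)=CCO	geraniol
CC(C)=CCCC(C)(O)C=C	linalool
CC1=CCC(CC1)C(C)(C)O	alpha-terpineol
CC(CCC=C(C)C)CCO	citronellol
CC(C)=CCCC(C)=CC=O	citral
CC1CCC(C(C)C)C(O)C1	menthol
CC1=CC(=O)CC(C)(C)C1	isophorone
CCCCC1CCC(=O)O1	gamma-nonalactone
CCCCCC1CCC(=O)O1	gamma-decalactone
CCCCCCC1CCC(=O)O1	gamma-undecalactone
CC1CCC(=O)O1	gamma-valerolactone
CC1=C(O)C(=O)CC1	cyclotene
CC1OC(=O)C(C)=C1O	sotolon
CC(=O)C(C)=O	diacetyl
CC(O)C(C)=O	acetoin
CCCCC=CC=O	2-heptenal
CC(C)C1=CC=C(C)C=C1	p-cymene
CC1=CC=C2C=CC=CC2=C1	2-methylnaphthalene
OCC(O)CO	glycerol
CCCCO	butanol
CCCO	propanol
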