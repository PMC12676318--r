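# Compact curated pan-assay interference (PAINS-class) catalog
# (version compact-1.0). Columns: pattern_id, SMARTS, description.
pattern_id	smarts	description
pains_quinone	[OX1]=C1C=CC(=[OX1])C=C1	para-quinone
pains_ortho_quinone	[OX1]=C1C(=[OX1])C=CC=C1	ortho-quinone
pains_catechol	[OX2H]c1ccccc1[OX2H]	catechol (redox-active diphenol)
pains_rhodanine	[SX1]=C1[NX3]C(=[OX1])CS1	rhodanine core
pains_ene_rhodanine	[SX1]=C1[NX3]C(=[OX1])C(=[CX3])S1	5-arylidene rhodanine
pains_azo_aryl	c[NX2]=[NX2]c	aryl azo dye
pains_hydrazone_aryl	c[CX3H0,CX3H1]=[NX2][NX3]	aryl hydrazone
pains_divinyl_ketone	[CX3]=[CX3][CX3](=[OX1])[CX3]=[CX3]	cross-conjugated dienone
pains_alkylidene_barbiturate	[CX3]=C1C(=O)NC(=O)NC1=O	alkylidene barbiturate
pains_aminothiophene	c1cc(sc1[NX3])	2-aminothiophene
pains_isothiazolone	S1C(=[OX1])[NX3]C=C1	isothiazolone
pains_mannich_phenol	[OX2H]c1ccccc1[CX4][NX3]	phenolic Mannich base
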