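# Compact curated structural-alert catalog, Brenk-class reactive/toxic
# fragments (version compact-1.0). Columns: pattern_id, SMARTS, description.
pattern_id	smarts	description
brenk_nitro_charged	[NX3+](=[OX1])[O-]	nitro group (charge-separated form)
brenk_nitro_neutral	[NX3](=[OX1])=[OX1]	nitro group (pentavalent form)
brenk_aldehyde	[CX3H1](=O)[#6]	aldehyde
brenk_michael_acceptor	[CX3]=[CX3][CX3]=[OX1]	alpha,beta-unsaturated carbonyl (Michael acceptor)
brenk_azo	[#6][NX2]=[NX2][#6]	azo compound
brenk_nitroso	[#6][NX2]=[OX1]	nitroso group
brenk_alkyl_halide	[CX4][Cl,Br,I]	alkyl halide
brenk_acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]	acyl halide
brenk_isocyanate	[NX2]=[CX2]=[OX1]	isocyanate
brenk_isothiocyanate	[NX2]=[CX2]=[SX1]	isothiocyanate
brenk_thiol	[SX2H]	thiol
brenk_disulfide	[SX2][SX2]	disulfide
brenk_peroxide	[OX2][OX2]	peroxide
brenk_hydrazine	[NX3][NX3]	hydrazine
brenk_oxime	[CX3]=[NX2][OX2H]	oxime
brenk_epoxide	[CX4]1[OX2][CX4]1	epoxide (three-membered O ring)
brenk_aziridine	[CX4]1[NX3][CX4]1	aziridine (three-membered N ring)
brenk_thioester	[CX3](=[OX1])[SX2]	thioester
brenk_dicarbonyl	[CX3](=[OX1])[CX3](=[OX1])	1,2-dicarbonyl
brenk_sulfonate_ester	[SX4](=[OX1])(=[OX1])[OX2][#6]	sulfonate ester
brenk_sulfonic_acid	[SX4](=[OX1])(=[OX1])[OX2H]	sulfonic acid
brenk_phosphorus	[#15]	phosphorus-containing group
brenk_quaternary_n	[NX4+]	quaternary nitrogen
brenk_imine	[#6][CX3]=[NX2][#6]	acyclic imine
brenk_triflate	[OX2][SX4](=[OX1])(=[OX1])C(F)(F)F	triflate
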