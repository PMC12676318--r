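ranking,id,affinity (kcal/mol),ld50 (mol/kg),BOILED-Egg region,P-gp substrate
RGZ,MCULE-8293284864,-8.5,2.713,HIA,-
1,MCULE-9385738471,-9.3,2.924,Out,-
2,MCULE-2321610882,-9.1,2.838,BBB,+
3,MCULE-2772386084,-9.1,2.805,HIA,-
4,MCULE-1323064686,-9.1,2.781,HIA,+
5,MCULE-1362639167,-9.0,2.721,BBB,+
6,MCULE-5835167846,-9.0,2.717,Out,+
7,MCULE-1302121223,-8.9,2.795,BBB,-
8,MCULE-1468861772,-8.7,2.774,BBB,-
9,MCULE-7373425071,-8.7,2.723,Out,-
10,MCULE-9059019223,-8.6,2.785,BBB,-
11,MCULE-7585853459,-8.6,2.721,HIA,-
12,MCULE-8688852980,-8.5,2.796,BBB,-
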