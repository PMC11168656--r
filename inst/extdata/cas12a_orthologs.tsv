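name	accession	host	length_aa	identity_to_lb_pct
BgCas12a	OLA11341.1	Bacteroides galacturonicus DSM 3978	1305	37.0
Fb2Cas12a	WP_089081092.1	Flavobacterium branchiophilum DSM 24789	1318	43.5
Fn3Cas12a	WP_004339290.1	Francisella tularensis novicida FTG, UT01-4992	1307	37.1
FsCas12a	WP_045971446.1	Flavobacterium sp. 316	1273	45.0
HoCas12a	TFF64011.1	Helcococcus ovis	1325	34.7
Lp2Cas12a	WP_055306762.1	Lachnospira pectinoschiza 2789STDY5834886	1305	37.3
Mb4Cas12a	WP_078273923.1	Moraxella bovis CCUG 2133	1261	41.5
Mb5Cas12a	WP_046700744.1	Moraxella bovoculi 58069	1251	39.9
MeCas12a	WP_079324973.1	Moraxella equi CCUG 4950	1251	40.6
Ml2Cas12a	WP_065256572.1	Moraxella lacunata CCUG 57757A	1264	40.8
Ml3Cas12a	WP_115006085.1	Moraxella lacunata	1261	37.5
MoCas12a	WP_112744621.1	Moraxella ovis NCTC 11019	1261	40.9
PiCas12a	WP_161942329.1	Prevotella ihumii Marseille-P3385	1320	43.6
Px2Cas12a	WP_151622887.1	Pseudobutyrivibrio xylanivorans MA3014 v2	1205	43.7
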