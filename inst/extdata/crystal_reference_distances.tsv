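structure	subunit_a	res_a	subunit_b	res_b	distance_A	note
1YVO	sTnC	13	sTnC	51	19.21	skeletal TnC N-domain closed (Ca-free)
1YTZ	sTnC	13	sTnC	51	29.06	skeletal TnC N-domain open (Ca-saturated)
1J1E	cTnC	13	cTnC	51	32.55	cardiac TnC N-domain, Ca-saturated crystal
1J1E	cTnC	67	cTnC	76	8.95	Ca-binding loop 2 termini (Asp67-Glu76)
1J1E	cTnI	131	cTnT	240	38.13	inter-subunit reference pair
1J1E	cTnI	131	cTnT	276	18.21	inter-subunit reference pair
1J1E	cTnI	160	cTnT	240	72.57	inter-subunit reference pair
1J1E	cTnI	129	cTnI	151	38.87	inhibitory-region end-to-end
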