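collection	sphere	libraries	peptides_millions	phe762	tyr762	leu762	total	normalized_printed
MgOl	Aquatic	79	366	236	342	617	1195	4
MgOl	Organismal	5	20	6	5	7	18	1
MgOl	Terrestrial	2	2	2	0	0	2	0
MgOl	Subtotal	86	388	244	347	624	1215	3
SERC	Aquatic	1	186	420	691	934	2045	11
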