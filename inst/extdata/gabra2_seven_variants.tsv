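# The seven GABRA2 (NM_000807.2 / NP_000798.2, UniProt P47869) missense
# variants associated with early infantile epileptic encephalopathy.
# Positions are 1-based on the canonical protein sequence.
gene	protein_id	pos	ref_aa	alt_aa	hgvs_c	hgvs_p	significance	source
GABRA2	GABRA2	263	M	T	NA	Met263Thr	pathogenic	manual
GABRA2	GABRA2	280	P	L	c.839C>T	Pro280Leu	pathogenic	manual
GABRA2	GABRA2	284	V	A	NA	Val284Ala	pathogenic	manual
GABRA2	GABRA2	291	L	V	NA	Leu291Val	pathogenic	manual
GABRA2	GABRA2	292	T	K	NA	Thr292Lys	pathogenic	manual
GABRA2	GABRA2	325	F	L	NA	Phe325Leu	pathogenic	manual
GABRA2	GABRA2	335	N	H	NA	Asn335His	pathogenic	manual
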