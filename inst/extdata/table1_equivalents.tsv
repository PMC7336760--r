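# Published pathogenic variants in other Cys-loop receptor genes at
# positions equivalent (or adjacent) to the seven GABRA2 study variants.
# equivalent_ref_pos is the published equivalent position on the GABRA2
# canonical sequence. 23 records under 6 of the 7 GABRA2 variants
# (Asn335His has no reported equivalent).
query_variant	gene	family	hgvs_c	hgvs_p	equivalent_ref_pos	rsid	source
Met263Thr	CHRNA2	nACh	c.836T>A	Ile279Asn	262	rs104894063	clinvar;humsavar
Met263Thr	GABRA1	GABA-A	c.788T>A	Met263Lys	263	rs796052491	clinvar
Met263Thr	GABRA1	GABA-A	c.789G>A	Met263Ile	263	rs1060499553	clinvar
Met263Thr	GABRA1	GABA-A	c.788T>C	Met263Thr	263	NA	manual
Met263Thr	GABRB3	GABA-A	c.766C>G	Leu256Val	263	rs1555401942	clinvar
Met263Thr	GABRB3	GABA-A	c.767T>A	Leu256Gln	263	NA	humsavar
Pro280Leu	GABRG2	GABA-A	c.905C>T	Pro302Leu	280	NA	manual
Pro280Leu	GLRA1	Gly	c.832C>A	Pro278Thr	280	rs121918413	clinvar;humsavar
Val284Ala	CHRNA2	nACh	c.889A>T	Ile297Phe	283	rs1554514507	clinvar
Val284Ala	GABRB2	GABA-A	c.830T>C	Leu277Ser	285	rs1554094145	clinvar
Val284Ala	GABRG2	GABA-A	c.919T>G	Leu307Val	285	rs796052509	clinvar
Leu291Val	CHRNB1	nACh	c.853C>A	Leu285Met	291	rs137852811	clinvar;humsavar
Leu291Val	GLRB	Gly	c.920_921delinsGA	Leu307Arg	291	NA	humsavar
Leu291Val	GABRA1	GABA-A	c.868G>A	Val290Met	290	rs796052494	clinvar
Leu291Val	GABRB2	GABA-A	c.845T>C	Val282Ala	290	rs886039374	clinvar
Leu291Val	GLRA1	Gly	c.862G>A	Val288Met	290	rs121918416	clinvar
Thr292Lys	GLRA1	Gly	c.869C>T	Thr290Ile	292	rs1064795411	clinvar
Thr292Lys	CHRNA4	nACh	c.851C>T	Ser284Leu	292	rs28931591	clinvar
Phe325Leu	CHRNB2	nACh	c.923T>C	Val308Ala	324	rs281865070	clinvar
Phe325Leu	GABRA1	GABA-A	c.973T>C	Phe325Leu	325	rs1064794681	clinvar
Phe325Leu	GABRB2	GABA-A	c.946G>A	Val316Ile	324	rs1554093884	clinvar
Phe325Leu	GABRB2	GABA-A	c.950_951delinsCA	Phe317Ser	325	rs1554093882	clinvar
Phe325Leu	CHRNA1	nACh	c.988G>A	Val330Ile	324	rs137852804	clinvar
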