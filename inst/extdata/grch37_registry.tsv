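# smnscreen locus registry, genome build GRCh37 (hg19, b37 coordinates, 1-based inclusive)
# gene intervals: RefSeq transcript spans, GRCh37 annotation (RefSeq curated, resolved 2026-09)
# site rows: paralog-discriminating positions; start/end give the SMN1 coordinate,
#   paired_position the analogous SMN2 coordinate; allele_smn1/allele_smn2 are the
#   GRCh37 reference bases at the SMN1 and SMN2 coordinates respectively
# variant rows: SMN1 duplication-associated polymorphisms (SMN1 g. numbering in label)
record_type	label	chromosome	start	end	paired_position	allele_smn1	allele_smn2	role	variant_class	alt_allele
site	a	5	70247724	70247724	69372304	A	G	discriminating	NA	NA
site	b	5	70247773	70247773	69372353	C	T	discriminating	NA	NA
site	c	5	70247921	70247921	69372501	A	G	discriminating	NA	NA
gene	SMN1	5	70220768	70248842	NA	NA	NA	target	NA	NA
gene	SMN2	5	69345348	69373422	NA	NA	NA	target	NA	NA
gene	ACAD9	3	128598332	128634910	NA	NA	NA	control	NA	NA
gene	ATR	3	142168077	142297668	NA	NA	NA	control	NA	NA
gene	CYP11B1	8	143953772	143961262	NA	NA	NA	control	NA	NA
gene	EDNRB	13	78469616	78493903	NA	NA	NA	control	NA	NA
gene	FASTKD2	2	207630080	207660913	NA	NA	NA	control	NA	NA
gene	FOXN1	17	26833260	26865914	NA	NA	NA	control	NA	NA
gene	HEXB	5	73935847	74018472	NA	NA	NA	control	NA	NA
gene	IQCB1	3	121488610	121553926	NA	NA	NA	control	NA	NA
gene	ITGA6	2	173292082	173371181	NA	NA	NA	control	NA	NA
gene	IVD	15	40697686	40713512	NA	NA	NA	control	NA	NA
gene	LMNA	1	156052369	156109880	NA	NA	NA	control	NA	NA
gene	LRPPRC	2	44113363	44223144	NA	NA	NA	control	NA	NA
gene	NTRK1	1	156785432	156851642	NA	NA	NA	control	NA	NA
gene	PTEN	10	89623195	89728532	NA	NA	NA	control	NA	NA
gene	RAB3GAP1	2	135809834	135928279	NA	NA	NA	control	NA	NA
gene	RAPSN	11	47459308	47470730	NA	NA	NA	control	NA	NA
gene	SIL1	5	138282409	138629246	NA	NA	NA	control	NA	NA
gene	SLC22A5	5	131705444	131731306	NA	NA	NA	control	NA	NA
gene	SLC35D1	1	67465014	67520080	NA	NA	NA	control	NA	NA
gene	STIM1	11	3875757	4114440	NA	NA	NA	control	NA	NA
variant	g.27134T>G	5	70247901	70247901	NA	T	NA	duplication	SNV	G
variant	g.27706_27707delAT	5	70248473	70248474	NA	AT	NA	duplication	deletion	NA
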