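ec	enzyme	gene_name	orf	expression_available
4.1.2.13	Fructose-bisphosphate aldolase	fbaI	Ot01g03020	TRUE
4.1.2.13	Fructose-bisphosphate aldolase	fbaI	Ot03g00610	TRUE
4.1.2.13	Fructose-bisphosphate aldolase	fbaII	Ot10g01490	TRUE
3.1.3.11	Fructose-1,6-bisphosphatase		Ot03g00330	TRUE
3.1.3.11	Fructose-1,6-bisphosphatase		Ot14g01140	TRUE
5.3.1.1	Triosephosphate isomerase		Ot09g00080	TRUE
5.3.1.9	Glucose-6-phosphate isomerase		Ot11g02980	TRUE
5.4.2.2	Phosphoglucomutase		Ot15g02630	TRUE
2.7.7.27	ADP-glucose pyrophosphorylase	AGPLU1	Ot07g03280	FALSE
2.7.7.27	ADP-glucose pyrophosphorylase	agpsu1	Ot07g02930	TRUE
2.7.7.27	ADP-glucose pyrophosphorylase	agplu2	Ot20g00490	FALSE
2.4.1.21	Soluble starch synthase	SSIII-C	Ot06g03410	FALSE
2.4.1.21	Soluble starch synthase	SSIII-B	Ot13g01250	TRUE
2.4.1.21	Soluble starch synthase	SSII	Ot16g02790	TRUE
2.4.1.21	Soluble starch synthase	SSI	Ot13g01230	TRUE
2.4.1.21	Soluble starch synthase	SSIII-A	Ot16g01560	TRUE
2.4.1.242	Granule-bound starch synthase	gbssI	Ot06g03200	TRUE
2.4.1.18	Starch branching enzyme	SBEII	Ot03g00840	TRUE
2.4.1.18	Starch branching enzyme	SBEI	Ot04g04110	TRUE
2.4.1.1	Starch phosphorylase		Ot11g00280	FALSE
2.4.1.1	Starch phosphorylase		Ot04g02110	TRUE
2.4.1.1	Starch phosphorylase	SPho1	Ot11g01020	FALSE
2.4.1.25	Disproportionating enzyme	DPE1	Ot02g05750	TRUE
2.4.1.25	Disproportionating enzyme		Ot11g02290	FALSE
2.4.1.25	Disproportionating enzyme		Ot11g02300	FALSE
3.2.1.1	Alpha-amylase	Aamy1	Ot16g00380	TRUE
3.2.1.1	Alpha-amylase		Ot02g05490	TRUE
3.2.1.1	Alpha-amylase	Aamy2	Ot10g00260	TRUE
3.2.1.1	Alpha-amylase	Aamy3	Ot07g02010	TRUE
3.2.1.2	Beta-amylase		Ot02g06980	TRUE
3.2.1.2	Beta-amylase	Bamy2	Ot03g03190	TRUE
3.2.1.2	Beta-amylase	bamy1	Ot03g03170	FALSE
3.2.1.68	Isoamylase (debranching enzyme)	dbe1 (Isa1)	Ot14g02550	TRUE
3.2.1.68	Isoamylase (debranching enzyme)	Isa2	Ot02g07230	FALSE
3.2.1.68	Isoamylase (debranching enzyme)	dbeII (Isa3)	Ot12g00310	TRUE
3.2.1.142	Pullulanase	spu	Ot01g03030	TRUE
2.7.9.4	Alpha-glucan, water dikinase (GWD)	SR1-A	Ot13g01510	TRUE
2.7.9.4	Alpha-glucan, water dikinase (GWD)	R1 C	Ot16g02370	FALSE
2.7.9.4	Alpha-glucan, water dikinase (GWD)		Ot04g04170	FALSE
	Glucose transporter		Ot03g05590	FALSE
	Glucose transporter		Ot14g01870	FALSE
	Glucose transporter		Ot08g01260	FALSE
	Maltose transporter	MEX1	Ot09g03160	TRUE
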