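#genome_id=synthetic_vertebrate_mito genome_length=16602
name	type	start	end	strand
tRNA-Phe	tRNA	1	69	+
12S-rRNA	rRNA	74	1023	+
tRNA-Val	tRNA	1024	1094	+
16S-rRNA	rRNA	1095	2774	+
tRNA-Leu	tRNA	2776	2849	+
ND1	CDS	2853	3824	+
tRNA-Ile	tRNA	3826	3895	+
tRNA-Gln	tRNA	3897	3967	-
tRNA-Met	tRNA	3968	4036	+
ND2	CDS	4040	5083	+
tRNA-Trp	tRNA	5084	5154	+
tRNA-Ala	tRNA	5159	5227	-
tRNA-Asn	tRNA	5231	5303	-
tRNA-Cys	tRNA	5305	5371	-
tRNA-Tyr	tRNA	5373	5442	-
COX1	CDS	5445	6995	+
tRNA-Ser2	tRNA	6996	7066	-
tRNA-Asp	tRNA	7067	7134	+
COX2	CDS	7137	7827	+
tRNA-Lys	tRNA	7831	7904	+
ATP8	CDS	7909	8076	+
ATP6	CDS	8081	8763	+
COX3	CDS	8768	9552	+
tRNA-Gly	tRNA	9556	9624	+
ND3	CDS	9626	9974	+
tRNA-Arg	tRNA	9978	10046	+
ND4L	CDS	10049	10345	+
ND4	CDS	10347	11727	+
tRNA-His	tRNA	11728	11796	+
tRNA-Ser1	tRNA	11798	11856	+
tRNA-Leu2	tRNA	11859	11931	+
ND5	CDS	11933	13771	+
ND6	CDS	13775	14296	-
tRNA-Glu	tRNA	14300	14368	-
CYTB	CDS	14370	15510	+
tRNA-Thr	tRNA	15515	15586	+
tRNA-Pro	tRNA	15590	15659	-
D-loop	D-loop	15664	16598	+
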