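symbol	gene_id	description	location	reference
ALDH1A2	8854	Aldehyde dehydrogenase 1 family member A2	15q21.3	B38
ALDH1L1	10840	Aldehyde dehydrogenase 1 family member L1	3q21.3	B46
AMBRA1	55626	Autophagy and beclin 1 regulator 1	11p11.2	B135
APAF1	317	Apoptotic peptidase activating factor 1	12q23.1	B121
APEX1	328	Apurinic/apyrimidinic endodeoxyribonuclease 1	14q11.2	B99
APOB	338	Apolipoprotein B	2p24.1	B143
BHMT	635	Betaine-homocysteine S-methyltransferase	5q14.1	B119
BMP4	652	Bone morphogenetic protein 4	14q22.2	B43
BRCA1	672	BRCA1, DNA repair associated	17q21.31	B68
CARM1	10498	Coactivator associated arginine methyltransferase 1	19p13.2	B79
CASP8	841	Caspase 8	2q33.1	B130
CBSL	875	Cystathionine beta-synthase	21q22.3	B87
CCL2	6347	C-C motif chemokine ligand 2	17q12	B60; B81
CDH2	1000	Cadherin 2	18q12.1	B53
CELSR1	9620	Cadherin EGF LAG seven-pass G-type receptor 1	22q13.31	B77
CFL1	1072	Cofilin 1	11q13.1	B140
CHKA	1119	Choline kinase alpha	11q13.2	B41
CITED2	10370	Cbp/p300 interacting transactivator with Glu/Asp rich carboxy-terminal domain 2	6q24.1	B79
COMT	1312	Catechol-O-methyltransferase	22q11.21	B26
CPE	1363	Carboxypeptidase E	4q32.3	B53
CREBBP	1387	CREB binding protein	16p13.3	B79
CSNK1G2	1455	Casein kinase 1 gamma 2	19p13.3	B53
CUBN	8029	Cubilin	10p13	B46
CYP26A1	1592	Cytochrome P450 family 26 subfamily A member 1	10q23.33	B105
DACT1	51339	Disheveled binding antagonist of beta catenin 1	14q23.1	B120
DDB1	1642	Damage specific DNA binding protein 1	11q12.2	B53
DHFR	1719	Dihydrofolate reductase	5q14.1	B87
DLC1	10395	DLC1 Rho GTPase activating protein	8p22	B72
DVL1	1855	Disheveled segment polarity protein 1	1p36.33	B27
DVL2	1856	Disheveled segment polarity protein 2	17p13.1	B35
EP300	2033	E1A binding protein p300	22q13.2	B79
ERCC2	2068	Xeroderma pigmentosum D	19q13.32	B99
FERMT2	10979	Fermitin family member 2	14q22.1	B53
FKBP8	23770	FKBP prolyl isomerase 8	19p13.11	B125
FOLH1	2346	Folate hydrolase 1	11p11.12	B51
FOLR1	2348	Folate receptor alpha	11q13.4	B44
FOLR2	2350	Folate receptor beta	11q13.4	B98
FOLR3	2352	Folate receptor gamma	11q13.4	B98
FOXN1	8456	Forkhead box N1	17q11.2	B5
FUZ	80199	Fuzzy planar cell polarity protein	19q13.33	B116
FZD3	7976	Frizzled class receptor 3	8p21.1	B117
FZD6	8323	Frizzled class receptor 6	8q22.3	B36; B63
GCKR	2646	Glucokinase regulator	2p23.3	B47
GLI2	2736	GLI family zinc finger 2	2q14.2	B80
GNAS	2778	GNAS complex locus	20q13.32	B138
GPC5	2262	Glypican 5	13q31.3	B10
GPR161	23432	G protein-coupled receptor 161	1q24.2	B67
GRHL3	57822	Grainyhead like transcription factor 3	1p36.11	B71
HK1	3098	Hexokinase 1	10q22.1	B33
HOXB7	3217	Homeobox B7	17q21.32	B112
ITGB1	3688	Integrin subunit beta 1	10p11.22	B72
ITPK1	3705	Inositol-tetrakisphosphate 1-kinase	14q32.12	B50
LEP	3952	Leptin	7q32.1	B82
LEPR	3953	Leptin receptor	1p31.3	B26; B122
LMNB1	4001	Lamin B1	5q23.2	B111
LRP6	4040	LDL receptor related protein 6	12p13.2	B74
MTHFD1	4522	Methylenetetrahydrofolate dehydrogenase, cyclohydrolase and formyltetrahydrofolate synthetase 1	14q23.3	B101
MTHFD1L	25902	Methylenetetrahydrofolate dehydrogenase (NADP+ dependent) 1 like	6q25.1	B102
MTHFD2	10797	Methylenetetrahydrofolate dehydrogenase (NADP+ dependent) 2	2p13.1	B119
MTHFR	4524	Methylenetetrahydrofolate reductase	1p36.22	B87; B26; B21
MTR	4548	5-methyltetrahydrofolate-homocysteine methyltransferase	1q43	B119
MTRR	4552	5-methyltetrahydrofolate-homocysteine methyltransferase reductase	5p15.31	B128
NAT1	9	N-acetyltransferase 1	8p22	B61
NCAM1	4684	Neural cell adhesion molecule 1	11q23.2	B37
NKX2-8	26257	NK2 homeobox 8	14q13.3	B114
NOG	9241	Noggin	17q22	B43
NOS3	4846	Nitric oxide synthase 3	7q36.1	B18
PAX1	5075	Paired box 1	20p11.22	B56
PAX3	5077	Paired box 3	2q36.1	B1
PCMT1	5110	Protein-L-isoaspartate (D-aspartate) O-methyltransferase	6q25.1	B142
PCYT1A	5130	Phosphate cytidylyltransferase 1, choline, alpha	3q29	B41
PDGFRA	5156	Platelet derived growth factor receptor alpha	4q12	B141; B26
PLCB1	23236	Phospholipase C beta 1	20p12.3	B53
PON1	5444	Paraoxonase 1	7q21.3	B49
PORCN	64840	Porcupine O-acyltransferase	Xp11.23	B53
PPP2R1A	5518	Protein phosphatase 2 scaffold subunit alpha	19q13.41	B53
PRICKLE1	144165	Prickle planar cell polarity protein 1	12q12	B15
PRICKLE2	166336	Prickle planar cell polarity protein 2	3p14.1	B53
PSMD3	5709	Proteasome 26S subunit, non-ATPase 3	17q21.1	B53
PTCH1	5727	Patched 1	9q22.32	B132
PTK7	5754	Protein tyrosine kinase 7	6p21.1	B75
PTPRS	5802	Protein tyrosine phosphatase receptor type S	19p13.3	B73
PTPRU	10076	Protein tyrosine phosphatase receptor type U	1p35.3	B53
RAD9B	144715	RAD9 checkpoint clamp component B	12q24.11	B25
RFC1	5981	Replication factor C subunit 1	4p14	B34
SARDH	1757	Sarcosine dehydrogenase	9q34.2	B46
SCRIB	23513	Scribbled planar cell polarity protein	8q24.3	B76
SDC1	6382	Syndecan 1	2p24.1	B53
SEC24B	10427	SEC24 homolog B, COPII coat complex component	4q25	B134
SHMT1	6470	Serine hydroxymethyltransferase 1	17p11.2	B109
SHROOM2	357	Shroom family member 2	Xp22.2	B29
SHROOM3	57619	Shroom family member 3	4q21.1	B73
SLC19A1	6573	Solute carrier family 19 member 1	21q22.3	B98
SLC2A1	6513	Solute carrier family 2 member 1	1p34.2	B33; B122
SMO	6608	Smoothened, frizzled class receptor	7q32.1	B131
SOD1	6647	Superoxide dismutase 1	21q22.11	B65; B64
SOD2	6648	Superoxide dismutase 2	6q25.3	B65; B64
SOSTDC1	25928	Sclerostin domain containing 1	7p21.2	B53
SOX18	54345	SRY-box transcription factor 18	20q13.33	B113
SOX3	6658	SRY-box transcription factor 3	Xq27.1	B11
T	6862	T-box transcription factor T	6q27	B26
TFAP2A	7020	Transcription factor AP-2 alpha	6p24.3	B79
TLE3	7090	TLE family member 3, transcriptional corepressor	15q23	B53
TNIP1	10318	TNFAIP3 interacting protein 1	5q33.1	B45
TNRC6B	23112	Trinucleotide repeat containing adaptor 6B	22q13.1	B53
TP53	7157	Tumor protein p53	17p13.1	B100
TRDMT1	1787	tRNA aspartic acid methyltransferase 1	10p13	B46
TRIM26	7726	Tripartite motif containing 26	6p22.1	B138
TRIM4	89122	Tripartite motif containing 4	7q22.1	B137
TRPM6	140803	Transient receptor potential cation channel subfamily M member 6	9q21.13	B115
TXN2	25828	Thioredoxin 2	22q12.3	B133
TYMS	7298	Thymidylate synthetase	18p11.32	B87; B119
UCP2	7351	Uncoupling protein 2	11q13.4	B129
VANGL1	81839	VANGL planar cell polarity protein 1	1p13.1	B9
VANGL2	57216	VANGL planar cell polarity protein 2	1q23.2	B66
ZIC2	7546	Zic family member 2	13q32.3	B69
ZIC3	7547	Zic family member 3	Xq26.3	B69
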