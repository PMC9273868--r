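gene	category	compartment	fals_value	sals_value	fals_p	sals_p	protein_family	tissue_enrichment	aging	proteomic	mechanism
ADRA2B	high_confidence	CNS	80	50	-	-	GPCR	Low tissue specificity	no	no	Protein degradation
CYBB	high_confidence	CNS	80	86	-	-	Ion channel	Blood, lung, lymphoid tissue	no	no	Oxidative stress
FLT1	high_confidence	CNS	80	57	-	-	Receptor kinase	Placenta	yes	no	Inflammation
MAP3K5	high_confidence	CNS	80	71	-	-	Protein kinase	Adrenal gland	yes	no	Apoptosis
MAPK1	high_confidence	CNS	80	71	-	-	CMGC kinase	Brain	no	no	Apoptosis
NOS1	high_confidence	CNS	80	86	-	-	Oxidoreductase	Brain and skeletal muscle	no	no	Oxidative stress
NR3C1	high_confidence	CNS	80	86	-	-	Nuclear receptor	Low tissue specificity	yes	no	Inflammation, excitotoxicity
PTK2	high_confidence	CNS	40	86	-	-	Tyrosine kinase	Low tissue specificity	yes	no	Protein aggregation
PTPRC	high_confidence	CNS	80	86	-	-	Receptor phosphatase	Blood, lymphoid tissue	no	no	Inflammation
RARA	high_confidence	CNS	50	14	-	-	Nuclear receptor	Low tissue specificity	no	no	Neurogenesis
AHCYL1	novel	CNS	100	71	-	-	Enzyme	Low tissue specificity	no	no	Apoptosis
KCNB2	novel	CNS	60	83	-	-	Ion channel	Brain, lymphoid tissue, pituitary gland	no	no	Excitotoxicity
P2RY14	novel	CNS	40	14	-	-	GPCR	Granulocytes, dendritic cells, placenta	no	no	Inflammation
SCYL1	novel	CNS	40	14	-	-	Protein kinase	Low tissue specificity	no	no	Apoptosis
SLC25A10	novel	CNS	20	29	-	-	Transporter	Liver	no	no	Oxidative stress
STUB1	novel	CNS	20	14	-	-	Acyltransferase	Low tissue specificity	yes	no	Protein degradation
DNMT3A	high_confidence	diMN	0.1324	0.0773	0.0346	0.1172	Methyltransferase	Low tissue specificity	no	no	Apoptosis
ERN1	high_confidence	diMN	0.2058	0.0699	0.003	0.1644	Protein kinase	Low tissue specificity	no	no	Protein aggregation, apoptosis
G6PD	high_confidence	diMN	-0.1416	-0.0847	0.0487	0.1337	Oxidoreductase	Testis	no	yes	Oxidative stress
HSPD1	high_confidence	diMN	0.1363	0.1916	0.1365	0.0083	Isomerase	Vagina	yes	yes	FUS pathology, inflammation
PPIA	high_confidence	diMN	0.1728	0.2361	0.0338	0.0003	Isomerase	Low tissue specificity	yes	yes	TDP-43 pathology, inflammation
RPS6KB1	high_confidence	diMN	0.1558	0.1426	0.0297	0.0052	AGC kinase	Low tissue specificity	no	no	Protein aggregation
VCP	high_confidence	diMN	0.0212	0.0776	0.637	0.0411	Hydrolase	Low tissue specificity	yes	yes	Mitochondrial dysfunction
KCNS3	novel	diMN	0.3886	0.3338	0.0995	0.0282	Ion channel	Skeletal muscle	no	no	Excitotoxicity
PPP3CB	novel	diMN	-0.3048	-0.1371	0.0115	0.1725	Esterase	Skeletal muscle	no	yes	Protein aggregate degradation
PSMC6	novel	diMN	-0.2636	-0.1502	0.0402	0.0926	Hydrolase	Low tissue specificity	no	yes	Proteostasis
METTL21A	novel	diMN	0.196	0.0827	0.0012	0.0432	Methyltransferase	Low tissue specificity	no	no	Protein aggregation
TOPORS	novel	diMN	0.2161	0.1385	0.0135	0.0184	Acyltransferase	Low tissue specificity	no	no	Apoptosis
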