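symbol	proto_oncogene	recessive_only	characteristic_tumors
AIP	0	0	pituitary_adenoma
ALK	1	0	neuroblastoma
APC	0	0	colorectal
ATM	0	0	breast
AXIN2	0	0	colorectal
BAP1	0	0	melanoma;kidney
BMPR1A	0	0	colorectal
BRCA1	0	0	breast;ovary
BRCA2	0	0	breast;ovary
BRIP1	0	0	ovary
CDC73	0	0	parathyroid_adenoma
CDH1	0	0	gastric;breast
CDK4	1	0	melanoma
CDKN1B	0	0	pituitary_adenoma;parathyroid_adenoma
CDKN2A	0	0	melanoma;pancreas
CDKN2B	0	0	
CEBPA	0	0	hem_myeloid
CHEK2	0	0	breast
CYLD	0	0	nmsc
DDB2	0	0	nmsc
DICER1	0	0	thyroid
EGFR	1	0	lung
EPCAM	0	0	colorectal;endometrium
ERCC2	0	1	nmsc
ERCC3	0	1	nmsc
ERCC4	0	1	nmsc
ERCC5	0	1	nmsc
EXT1	0	0	bone_sarcoma
EXT2	0	0	bone_sarcoma
FH	0	0	cutaneous_leiomyoma;uterine_leiomyoma;kidney
FLCN	0	0	kidney;pulmonary_lam
GATA2	0	0	hem_myeloid
HFE	0	1	liver
HNF1A	0	0	liver
KIT	1	0	gist
MAX	0	0	pheochromocytoma
MEN1	0	0	pituitary_adenoma;parathyroid_adenoma;pnet
MET	1	0	kidney
MLH1	0	0	colorectal;endometrium
MSH2	0	0	colorectal;endometrium
MSH6	0	0	colorectal;endometrium
MUTYH	0	1	colorectal
NF1	0	0	soft_tissue_sarcoma;cns;pheochromocytoma
NF2	0	0	cns
NTHL1	0	1	colorectal
PALB2	0	0	breast
PDGFRA	1	0	gist
PHOX2B	0	0	neuroblastoma
PMS2	0	0	colorectal;endometrium
POLD1	0	0	colorectal
POLE	0	0	colorectal
POLH	0	1	nmsc
PRKAR1A	0	0	adrenocortical
PTCH1	0	0	nmsc
PTEN	0	0	breast;thyroid;endometrium
RAD51C	0	0	ovary
RAD51D	0	0	ovary
RB1	0	0	retinoblastoma;bone_sarcoma
RET	1	0	medullary_thyroid;pheochromocytoma
RHBDF2	1	0	
RUNX1	0	0	hem_myeloid
SDHA	0	0	paraganglioma;pheochromocytoma;gist
SDHAF2	0	0	paraganglioma
SDHB	0	0	paraganglioma;pheochromocytoma;kidney
SDHC	0	0	paraganglioma;gist
SDHD	0	0	paraganglioma;pheochromocytoma
SERPINA1	0	1	liver
SMAD4	0	0	colorectal
SMARCA4	0	0	ovary
SMARCB1	0	0	cns
SMARCE1	0	0	cns
SRY	0	0	
STK11	0	0	colorectal;breast
SUFU	0	0	cns
TGFBR1	0	0	colorectal
TMEM127	0	0	pheochromocytoma
TP53	0	0	breast;soft_tissue_sarcoma;adrenocortical;cns
TSC1	0	0	kidney;cns
TSC2	0	0	kidney;cns
VHL	0	0	kidney;pheochromocytoma;cns
WT1	0	0	wilms_tumor
XPA	0	1	nmsc;melanoma
XPC	0	1	nmsc;melanoma
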