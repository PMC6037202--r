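category	malignant	cns
breast	1	0
colorectal	1	0
kidney	1	0
nmsc	1	0
ovary	1	0
endometrium	1	0
melanoma	1	0
thyroid	1	0
medullary_thyroid	1	0
lung	1	0
hem_lymphoid	1	0
hem_myeloid	1	0
soft_tissue_sarcoma	1	0
bone_sarcoma	1	0
pituitary_adenoma	0	0
cns	0	1
pheochromocytoma	0	0
paraganglioma	0	0
cutaneous_leiomyoma	0	0
uterine_leiomyoma	0	0
pulmonary_lam	0	0
testicular	1	0
prostate	1	0
small_bowel	1	0
gi_net	1	0
pnet	1	0
pancreas	1	0
gastric	1	0
bladder	1	0
cervix	1	0
parathyroid_adenoma	0	0
adrenocortical	1	0
wilms_tumor	1	0
retinoblastoma	1	0
neuroblastoma	1	0
gist	1	0
liver	1	0
other	1	0
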