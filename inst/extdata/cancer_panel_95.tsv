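symbol	inheritance	haploinsufficient	acmg_sf	cancer_types	transcript
APC	AD	yes	TRUE	colorectal;desmoid	
BMPR1A	AD	yes	TRUE	colorectal;gastric	
BRCA1	AD	yes	TRUE	breast;ovarian;pancreatic	NM_007300.4
BRCA2	AD	yes	TRUE	breast;ovarian;pancreatic;prostate	NM_000059.3
MEN1	AD	yes	TRUE	endocrine;pancreatic	
MLH1	AD	yes	TRUE	colorectal;endometrial;ovarian	
MSH2	AD	yes	TRUE	colorectal;endometrial;ovarian	NM_000251.3
MSH6	AD	yes	TRUE	colorectal;endometrial;ovarian	NM_000179.3
MUTYH	AR	yes	TRUE	colorectal	
NF2	AD	yes	TRUE	nervous_system	
PMS2	AD	yes	TRUE	colorectal;endometrial;ovarian	
PTEN	AD	yes	TRUE	breast;thyroid;endometrial	
RB1	AD	yes	TRUE	retinoblastoma;sarcoma	
RET	AD	no	TRUE	thyroid;endocrine	
SDHAF2	AD	yes	TRUE	paraganglioma	
SDHB	AD	yes	TRUE	paraganglioma;kidney	
SDHC	AD	yes	TRUE	paraganglioma	
SDHD	AD	yes	TRUE	paraganglioma	
SMAD4	AD	yes	TRUE	colorectal;gastric	
STK11	AD	yes	TRUE	colorectal;breast;pancreatic	
TP53	AD	yes	TRUE	breast;sarcoma;brain;adrenal	
TSC1	AD	yes	TRUE	kidney;brain	
TSC2	AD	yes	TRUE	kidney;brain	
VHL	AD	yes	TRUE	kidney;paraganglioma	
WT1	AD	yes	TRUE	kidney	
AIP	AD	yes	FALSE	endocrine	
ALK	AD	no	FALSE	neuroblastoma	
ATM	AD	yes	FALSE	breast;pancreatic	NM_000051.3
AXIN2	AD	yes	FALSE	colorectal	NM_004655.4
BAP1	AD	yes	FALSE	melanoma;mesothelioma;kidney	
BARD1	AD	yes	FALSE	breast	NM_000465.4
BLM	AR	yes	FALSE	leukemia;colorectal	
BRIP1	AD	yes	FALSE	ovarian;breast	NM_032043.3
BUB1B	AR	yes	FALSE	sarcoma	
CDC73	AD	yes	FALSE	endocrine	
CDH1	AD	yes	FALSE	gastric;breast	
CDK4	AD	no	FALSE	melanoma	
CDKN1B	AD	yes	FALSE	endocrine	
CDKN2A	AD	yes	FALSE	melanoma;pancreatic	
CEBPA	AD	unknown	FALSE	leukemia	
CHEK2	AD	yes	FALSE	breast;colorectal;prostate	NM_007194.4
CYLD	AD	yes	FALSE	skin_appendage	
DDB2	AR	yes	FALSE	skin	
DICER1	AD	yes	FALSE	thyroid;lung;ovarian	NM_030621.4
DIS3L2	AR	unknown	FALSE	kidney	
EPCAM	AD	yes	FALSE	colorectal;endometrial	
ERCC2	AR	yes	FALSE	skin	
ERCC3	AR	yes	FALSE	skin	
ERCC4	AR	yes	FALSE	skin	
ERCC5	AR	yes	FALSE	skin	
EXT1	AD	yes	FALSE	sarcoma	
EXT2	AD	yes	FALSE	sarcoma	
FANCA	AR	yes	FALSE	leukemia	
FANCB	XL	yes	FALSE	leukemia	
FANCC	AR	yes	FALSE	leukemia	
FANCD2	AR	yes	FALSE	leukemia	
FANCE	AR	yes	FALSE	leukemia	
FANCF	AR	yes	FALSE	leukemia	
FANCG	AR	yes	FALSE	leukemia	
FH	AD	yes	FALSE	kidney;uterine_leiomyoma	
FLCN	AD	yes	FALSE	kidney	
GATA2	AD	yes	FALSE	leukemia	
GPC3	XL	yes	FALSE	wilms;liver	NM_001164617.2
HOXB13	AD	no	FALSE	prostate	
HRAS	AD	no	FALSE	bladder;thyroid	
KIT	AD	no	FALSE	gastrointestinal_stromal	
LZTR1	AD	yes	FALSE	schwannoma	NM_006767.4
MAX	AD	no	FALSE	paraganglioma	
MITF	AD	no	FALSE	melanoma;kidney	
MRE11	AR	yes	FALSE	breast	
NBN	AD	yes	FALSE	breast;leukemia	NM_002485.5
NF1	AD	yes	FALSE	nervous_system;breast	
NTHL1	AR	yes	FALSE	colorectal;breast	
PALB2	AD	yes	FALSE	breast;pancreatic	NM_024675.4
PDGFRA	AD	no	FALSE	gastrointestinal_stromal	
PHOX2B	AD	unknown	FALSE	neuroblastoma	
POLD1	AD	no	FALSE	colorectal;endometrial	
POLE	AD	no	FALSE	colorectal	
POT1	AD	yes	FALSE	melanoma;glioma	NM_015450.3
PRKAR1A	AD	yes	FALSE	endocrine;myxoma	
PTCH1	AD	yes	FALSE	skin;brain	
RAD50	AD	yes	FALSE	breast	NM_005732.4
RAD51C	AD	yes	FALSE	ovarian;breast	NM_058216.3
RAD51D	AD	yes	FALSE	ovarian;breast	NM_002878.3
RECQL4	AR	yes	FALSE	sarcoma;skin	
RUNX1	AD	yes	FALSE	leukemia	
SDHA	AD	yes	FALSE	paraganglioma;gastrointestinal_stromal	
SMARCA4	AD	yes	FALSE	ovarian	
SMARCB1	AD	yes	FALSE	rhabdoid;schwannoma	
SMARCE1	AD	yes	FALSE	meningioma	
SUFU	AD	yes	FALSE	brain;skin	NM_016169.4
TERT	AD	unknown	FALSE	melanoma;leukemia	
TMEM127	AD	yes	FALSE	paraganglioma	
WRN	AR	yes	FALSE	sarcoma;thyroid;melanoma	
XPC	AR	unknown	FALSE	skin	
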