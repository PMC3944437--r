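gene	division	category
FN1	core_matrisome	ECM_glycoproteins
POSTN	core_matrisome	ECM_glycoproteins
TNC	core_matrisome	ECM_glycoproteins
LTBP3	core_matrisome	ECM_glycoproteins
SNED1	core_matrisome	ECM_glycoproteins
LAMA3	core_matrisome	ECM_glycoproteins
LAMB1	core_matrisome	ECM_glycoproteins
LAMC1	core_matrisome	ECM_glycoproteins
NID1	core_matrisome	ECM_glycoproteins
VTN	core_matrisome	ECM_glycoproteins
FGA	core_matrisome	ECM_glycoproteins
FGB	core_matrisome	ECM_glycoproteins
FGG	core_matrisome	ECM_glycoproteins
EFEMP2	core_matrisome	ECM_glycoproteins
TINAGL1	core_matrisome	ECM_glycoproteins
AGRN	core_matrisome	proteoglycans
HSPG2	core_matrisome	proteoglycans
COL1A1	core_matrisome	collagens
COL1A2	core_matrisome	collagens
COL4A1	core_matrisome	collagens
COL5A1	core_matrisome	collagens
COL6A1	core_matrisome	collagens
COL6A2	core_matrisome	collagens
COL6A3	core_matrisome	collagens
COL18A1	core_matrisome	collagens
ANXA2	matrisome_associated	ECM_affiliated
LGALS1	matrisome_associated	ECM_affiliated
C1QA	matrisome_associated	ECM_affiliated
CTSB	matrisome_associated	ECM_regulators
LOXL2	matrisome_associated	ECM_regulators
MMP2	matrisome_associated	ECM_regulators
TGM2	matrisome_associated	ECM_regulators
SERPINE2	matrisome_associated	ECM_regulators
TIMP1	matrisome_associated	ECM_regulators
EGLN1	matrisome_associated	ECM_regulators
PLG	matrisome_associated	ECM_regulators
F2	matrisome_associated	ECM_regulators
S100A2	matrisome_associated	secreted_factors
S100A10	matrisome_associated	secreted_factors
ANGPTL4	matrisome_associated	secreted_factors
CTGF	matrisome_associated	secreted_factors
CYR61	matrisome_associated	secreted_factors
IGFBP4	matrisome_associated	secreted_factors
VWF	matrisome_associated	secreted_factors
GAPDH	non_matrisome	none
ACTB	non_matrisome	none
VIM	non_matrisome	none
TFRC	non_matrisome	none
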