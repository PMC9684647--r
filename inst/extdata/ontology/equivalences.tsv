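lobe_group	hhoa_pu	hhoa_name	human_ba	mhoa_pu	monkey_ba	walker	footnotes
frontal	COa	Central opercular cortex - anterior	43	COa	43*	n.d.	
frontal	F1La	Superior frontal gyrus, lateral, anterior	8, 9	F1dls	9 (6, 8)	9, 8B	
frontal	F1Lm	Superior frontal gyrus, lateral, middle	8 (9, 6)	F1dls	9 (6, 8)	9, 8B	
frontal	F1Lp	Superior frontal gyrus, lateral, posterior	6	PMd	6	6	
frontal	F1m	Superior frontal gyrus, medial	8 (9)	F1dm	6 (32)	6, 8B, 9	
frontal	F2a	Middle frontal gyrus, anterior	46, 10 (9)	F1dli	9, 8 (10)	46 (8A)	
frontal	F2m	Middle frontal gyrus, middle	8, 9 (46)	F1dli	9, 8 (10)	46 (8A)	
frontal	F2p	Middle frontal gyrus, posterior	6	PMd	6	6	
frontal	F3a	Inferior frontal gyrus, anterior	10, 46	F2	10, 9, 8	12, 45, 46	
frontal	F3o	Inferior frontal gyrus, pars opercularis	44	F2	10, 9, 8	12, 45, 46	
frontal	F3orb	Inferior frontal gyrus, pars orbitalis	47	F2	10, 9, 8	12, 45, 46	
frontal	F3t	Inferior frontal gyrus, pars triangularis	45	F2	10, 9, 8	12, 45, 46	
frontal	FMC	Frontal medial cortex	11	FMC	9, 11, 12	14, 25 (10)	
frontal	FO	Frontal opercular cortex	44, 45	COa	n.d.**	n.d.	
frontal	FOCa	Frontal orbital cortex, anterior	11	FOCa	9, 10, 11, 12	11 (10)	inferred
frontal	FOCL	Frontal orbital cortex, lateral	11	FOCL	10 (11)	12 (11)	inferred
frontal	FOCm	Frontal orbital cortex, medial	11	FOCm	9, 11, 12	14 (10)	inferred
frontal	FOCp	Frontal orbital cortex, posterior	11	FOCp	11 (9)	13	inferred;walker13
frontal	FPL	Frontal pole, lateral	10 (9, 11)	FP	9, 12	10	
frontal	FPm	Frontal pole, medial	10 (9, 11)	FP	9, 12	10	
frontal	PreSMAi	Pre-supplementary motor area, inferior	6 (medial)	PreSMA	4 (6)	n.d.	
frontal	PreSMAs	Pre-supplementary motor area, superior	6 (medial), 32	PreSMA	4 (6)	n.d.	
frontal	PRGLi	Precentral gyrus, lateral, inferior	4, 6	PRGL, PMv	4 (PRGL), 6 (PMv)	n.d.	
frontal	PRGLm	Precentral gyrus, lateral, middle	4, 6	PRGL	4	n.d.	
frontal	PRGLs	Precentral gyrus, lateral, superior	4 (6)	PRGL	4	n.d.	
frontal	PRGm	Precentral gyrus, medial	4 (medial)	PRGm/SMA	4 (3)	n.d.	
frontal	SMA	Supplementary motor area	4 (medial), 6 (medial)	PRGm/SMA	4, 3	n.d.	
occipital	CALCi	Intracalcarine cortex, inferior	17	CALCi	17		
occipital	CALCs	Intracalcarine cortex, superior	17	CALCs	17		
occipital	CN	Cuneal cortex	18, 19	STRm	17, 18 (19)		
occipital	LG	Lingual gyrus	18, 19 (17)	VMO	19, 20 (18)		
occipital	OF	Occipital fusiform gyrus	19	VMO	19, 20 (18)		
occipital	OLi	Lateral occipital cortex, inferior	18, 19 (37)	VMO	19, 20 (18)		
occipital	OLs	Lateral occipital cortex, superior	18, 19	PRL	18, 19		
occipital	OP	Occipital pole	17, 18	STRdli, STRdls	17 (18)		
occipital	SCALC	Supracalcarine cortex	17 (18)	STRm	17, 18		
parietal	AGa	Angular gyrus, anterior	39 (anterior)	LPCi	7		
parietal	AGp	Angular gyrus, posterior	39 (posterior)	LPCi	7		
parietal	COp	Central opercular cortex, posterior	43	COp	43*		
parietal	PCN	Precuneal cortex	7 (medial) (31)	MPC	7, 19 (18)		
parietal	PO	Parietal opercular cortex	40	PO	7		inferred
parietal	POGLi	Postcentral gyrus, lateral, inferior	3, 1, 2	POGL	3, 1, 2 (5)		
parietal	POGLm	Postcentral gyrus, lateral, middle	3, 1, 2 (5)	POGL	3, 1, 2 (5)		
parietal	POGLs	Postcentral gyrus, lateral, superior	3, 1, 2 (5)	POGL	3, 1, 2 (5)		
parietal	POGm	Postcentral gyrus, medial	3, 1, 2 (5)	POGm	3, 1, 2 (5)		
parietal	SGa	Supramarginal gyrus, anterior	40	LPCi	7		
parietal	SGp	Supramarginal gyrus, posterior	40, 22	LPCi	7		
parietal	SPLa	Superior parietal lobule, anterior	7 (5)	LPCs	7, 5		
parietal	SPLp	Superior parietal lobule, posterior	7	LPCs	7, 5		
temporal	H1	Heschl's gyrus	41	STPp	22		
temporal	INSa	Insular cortex, anterior	J ant (agranular)	INS	14, 15, 16 (agranular)		dysgranular
temporal	INSp	Insular cortex, posterior	J post (granular)	INS	13 (granular)		ba13-walker;dysgranular
temporal	PP	Planum polare	22 (anterior)	STPa	22		
temporal	PT	Planum temporale	22 (posterior), 42	STPp	22		
temporal	T1a	Superior temporal gyrus, anterior	22 (anterior)	STG	22		t1a-borders
temporal	T1p	Superior temporal gyrus, posterior	22 (posterior)	STG	22		
temporal	T2a	Middle Temporal gyrus, anterior	21 (anterior)	ITG	20, 21 (19)		
temporal	T2p	Middle temporal gyrus, posterior	21 (posterior), (22)	ITG	20, 21 (19)		
temporal	T3a	Inferior temporal gyrus, anterior	20 (anterior)	ITG	20, 21 (19)		
temporal	T3p	Inferior temporal gyrus, posterior	20 (posterior) (37)	ITG	20, 21 (19)		
temporal	TFa	Temporal fusiform cortex, anterior	20, 36	ITG	20, 21 (19)		
temporal	TFp	Temporal fusiform cortex, posterior	20, 36	ITG	20, 21 (19)		
temporal	TO2	Middle temporal gyrus, temporo-occipital	37	ITG	20, 21 (19)		
temporal	TO3	Inferior temporal gyrus, temporo-occipital	37	ITG	20, 21 (19)		
temporal	TOF	Temporal occipital fusiform cortex	37	VMO	19, 20 (18)		
temporal	TP	Temporal pole	38	TP	21, 22, 28		
paralimbic	CGa_a	Cingulate gyrus, anterior, anterior part	33, 24	CGa	24 (23, 32)		
paralimbic	CGa_p	Cingulate gyrus, anterior, posterior part	33, 24	CGa	24 (23, 32)		
paralimbic	CGp	Cingulate gyrus, posterior	23, 31, 26, 29, 30	CGp	23, 26 (18, 19)		
paralimbic	PAC	Paracingulate gyrus	32	F1dm	6, 9, 32		
paralimbic	PHa	Parahippocampal gyrus, anterior	28, 34	PH	19, 20, 21, 27		
paralimbic	PHp	Parahippocampal gyrus, posterior	27, 35	PH	19, 20, 21, 27		
paralimbic	SC	Subcallosal cortex	25, 32 (24)	SC	24 (32)		
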