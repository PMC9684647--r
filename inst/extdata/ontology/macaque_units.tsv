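id	name	lobe	modified
CALCi	Intracalcarine cortex, inferior	occipital	TRUE
CALCs	Intracalcarine cortex, superior	occipital	TRUE
CGa	Cingulate gyrus, anterior	paralimbic	FALSE
CGp	Cingulate gyrus, posterior	paralimbic	FALSE
COa	Central opercular cortex, anterior	frontal	FALSE
COp	Central opercular cortex, posterior	parietal	FALSE
F1dli	Middle frontal gyrus	frontal	TRUE
F1dls	Superior frontal gyrus	frontal	FALSE
F1dm	Superior frontal gyrus, medial	frontal	FALSE
F2	Inferior frontal gyrus	frontal	FALSE
FMC	Frontal medial cortex	frontal	TRUE
FOCa	Frontal orbital cortex, anterior	frontal	TRUE
FOCL	Frontal orbital cortex, lateral	frontal	TRUE
FOCm	Frontal orbital cortex, medial	frontal	TRUE
FOCp	Frontal orbital cortex, posterior	frontal	TRUE
FP	Frontal pole	frontal	FALSE
INS	Insular cortex	insular	FALSE
ITG	Inferior temporal gyrus	temporal	FALSE
LPCi	Lateral parietal cortex, inferior	parietal	FALSE
LPCs	Lateral parietal cortex, superior	parietal	FALSE
MPC	Medial parietal cortex	parietal	FALSE
PH	Parahippocampal gyrus	paralimbic	FALSE
PO	Parietal opercular cortex	parietal	FALSE
POGL	Postcentral gyrus, lateral	parietal	TRUE
POGm	Postcentral gyrus, medial	parietal	TRUE
PMd	Premotor cortex, dorsal	frontal	TRUE
PMv	Premotor cortex, ventral	frontal	TRUE
PreSMA	Pre-supplementary motor area	frontal	TRUE
PRGL	Precentral gyrus, lateral	frontal	TRUE
PRGm/SMA	Precentral gyrus, medial/supplementary motor area	frontal	TRUE
PRL	Prelunate gyrus	occipital	FALSE
SC	Subcallosal cortex	paralimbic	FALSE
STG	Superior temporal gyrus	temporal	FALSE
STPa	Supratemporal plane, anterior	temporal	TRUE
STPp	Supratemporal plane, posterior	temporal	TRUE
STRdli	Striate cortex, dorsolateral, inferior	occipital	TRUE
STRdls	Striate cortex, dorsolateral, superior	occipital	TRUE
STRm	Striate cortex, medial	occipital	FALSE
TP	Temporal pole	temporal	FALSE
VMO	Ventromedial occipital cortex	occipital	FALSE
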