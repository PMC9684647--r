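id	name	lobe	modified
AGa	Angular gyrus, anterior	parietal	TRUE
AGp	Angular gyrus, posterior	parietal	TRUE
CALCi	Intracalcarine cortex, inferior	occipital	TRUE
CALCs	Intracalcarine cortex, superior	occipital	TRUE
CGa_a	Cingulate gyrus, anterior, anterior part	paralimbic	TRUE
CGa_p	Cingulate gyrus, anterior, posterior part	paralimbic	TRUE
CGp	Cingulate gyrus, posterior	paralimbic	FALSE
CN	Cuneal cortex	occipital	FALSE
COa	Central opercular cortex, anterior	frontal	TRUE
COp	Central opercular cortex, posterior	parietal	TRUE
F1La	Superior frontal gyrus, lateral, anterior	frontal	TRUE
F1Lm	Superior frontal gyrus, lateral, middle	frontal	TRUE
F1Lp	Superior frontal gyrus, lateral, posterior	frontal	TRUE
F1m	Superior frontal gyrus, medial	frontal	TRUE
F2a	Middle frontal gyrus, anterior	frontal	TRUE
F2m	Middle frontal gyrus, middle	frontal	TRUE
F2p	Middle frontal gyrus, posterior	frontal	TRUE
F3a	Inferior frontal gyrus, anterior	frontal	TRUE
F3o	Inferior frontal gyrus, pars opercularis	frontal	FALSE
F3orb	Inferior frontal gyrus, pars orbitalis	frontal	TRUE
F3t	Inferior frontal gyrus, pars triangularis	frontal	FALSE
FMC	Frontal medial cortex	frontal	FALSE
FO	Frontal opercular cortex	frontal	FALSE
FOCa	Frontal orbital cortex, anterior	frontal	TRUE
FOCL	Frontal orbital cortex, lateral	frontal	TRUE
FOCm	Frontal orbital cortex, medial	frontal	TRUE
FOCp	Frontal orbital cortex, posterior	frontal	TRUE
FPL	Frontal pole, lateral	frontal	TRUE
FPm	Frontal pole, medial	frontal	TRUE
H1	Heschl's gyrus	temporal	FALSE
INSa	Insular cortex, anterior	insular	TRUE
INSp	Insular cortex, posterior	insular	TRUE
LG	Lingual gyrus	occipital	FALSE
OF	Occipital fusiform gyrus	occipital	FALSE
OLi	Lateral occipital cortex, inferior	occipital	FALSE
OLs	Lateral occipital cortex, superior	occipital	FALSE
OP	Occipital pole	occipital	FALSE
PAC	Paracingulate gyrus	paralimbic	FALSE
PCN	Precuneal cortex	parietal	FALSE
PHa	Parahippocampal gyrus, anterior	paralimbic	FALSE
PHp	Parahippocampal gyrus, posterior	paralimbic	FALSE
PO	Parietal opercular cortex	parietal	FALSE
POGLi	Postcentral gyrus, lateral, inferior	parietal	TRUE
POGLm	Postcentral gyrus, lateral, middle	parietal	TRUE
POGLs	Postcentral gyrus, lateral, superior	parietal	TRUE
POGm	Postcentral gyrus, medial	parietal	TRUE
PP	Planum polare	temporal	FALSE
PreSMAi	Pre-supplementary motor area, inferior	frontal	TRUE
PreSMAs	Pre-supplementary motor area, superior	frontal	TRUE
PRGLi	Precentral gyrus, lateral, inferior	frontal	TRUE
PRGLm	Precentral gyrus, lateral, middle	frontal	TRUE
PRGLs	Precentral gyrus, lateral, superior	frontal	TRUE
PRGm	Precentral gyrus, medial	frontal	TRUE
PT	Planum temporale	temporal	FALSE
SC	Subcallosal cortex	paralimbic	FALSE
SCALC	Supracalcarine cortex	occipital	FALSE
SGa	Supramarginal gyrus, anterior	parietal	FALSE
SGp	Supramarginal gyrus, posterior	parietal	FALSE
SMA	Supplementary motor area	frontal	FALSE
SPLa	Superior parietal lobule, anterior	parietal	TRUE
SPLp	Superior parietal lobule, posterior	parietal	TRUE
T1a	Superior temporal gyrus, anterior	temporal	FALSE
T1p	Superior temporal gyrus, posterior	temporal	FALSE
T2a	Middle temporal gyrus, anterior	temporal	FALSE
T2p	Middle temporal gyrus, posterior	temporal	FALSE
T3a	Inferior temporal gyrus, anterior	temporal	FALSE
T3p	Inferior temporal gyrus, posterior	temporal	FALSE
TFa	Temporal fusiform cortex, anterior	temporal	FALSE
TFp	Temporal fusiform cortex, posterior	temporal	FALSE
TO2	Middle temporal gyrus, temporo-occipital	temporal	FALSE
TO3	Inferior temporal gyrus, temporo-occipital	temporal	FALSE
TOF	Temporal occipital fusiform cortex	temporal	FALSE
TP	Temporal pole	temporal	FALSE
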