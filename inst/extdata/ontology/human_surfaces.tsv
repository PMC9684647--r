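pu	classes
AGa	lateral
AGp	lateral
CALCi	medial
CALCs	medial
CGa_a	medial
CGa_p	medial
CGp	medial
CN	medial
COa	opercular
COp	opercular
F1La	lateral
F1Lm	lateral
F1Lp	lateral
F1m	medial
F2a	lateral
F2m	lateral
F2p	lateral
F3a	lateral
F3o	lateral;ventral
F3orb	lateral
F3t	lateral
FMC	ventral
FO	opercular
FOCa	ventral
FOCL	ventral
FOCm	ventral
FOCp	ventral
FPL	lateral
FPm	medial
H1	opercular
INSa	insular
INSp	insular
LG	medial;ventral
OF	ventral
OLi	lateral;ventral
OLs	lateral
OP	lateral;medial;ventral
PAC	medial
PCN	medial
PHa	ventral
PHp	ventral
PO	opercular
POGLi	lateral
POGLm	lateral
POGLs	lateral
POGm	medial
PP	opercular
PreSMAi	medial
PreSMAs	medial
PRGLi	lateral
PRGLm	lateral
PRGLs	lateral
PRGm	medial
PT	opercular
SC	ventral
SCALC	medial
SGa	lateral
SGp	lateral
SMA	medial
SPLa	lateral
SPLp	lateral
T1a	lateral
T1p	lateral
T2a	lateral
T2p	lateral
T3a	lateral;ventral
T3p	lateral;ventral
TFa	ventral
TFp	ventral
TO2	lateral
TO3	lateral;ventral
TOF	ventral
TP	lateral;ventral;opercular
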