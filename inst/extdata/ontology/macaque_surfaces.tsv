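pu	classes
CALCi	medial
CALCs	medial
CGa	medial
CGp	medial
COa	opercular
COp	opercular
F1dli	lateral
F1dls	lateral
F1dm	medial
F2	lateral
FMC	ventral
FOCa	ventral
FOCL	ventral
FOCm	ventral
FOCp	ventral
FP	lateral;medial
INS	insular
ITG	lateral;ventral
LPCi	lateral
LPCs	lateral
MPC	medial
PH	ventral
PO	opercular
POGL	lateral
POGm	medial
PMd	lateral
PMv	lateral
PreSMA	medial
PRGL	lateral
PRGm/SMA	medial
PRL	lateral
SC	ventral
STG	lateral
STPa	opercular
STPp	opercular
STRdli	lateral;ventral;medial
STRdls	lateral
STRm	medial
TP	lateral;opercular
VMO	ventral;medial
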