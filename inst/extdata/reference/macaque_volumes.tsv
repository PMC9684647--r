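pu	right_cm3	left_cm3
CALCi	0.51	0.49
CALCs	0.72	0.72
CGa	0.72	0.80
CGp	0.40	0.45
COa	0.19	0.20
COp	0.19	0.20
F1dli	0.61	0.53
F1dls	0.29	0.28
F1dm	0.28	0.25
F2	0.58	0.65
FMC	0.19	0.23
FOCa	0.20	0.14
FOCL	0.35	0.31
FOCm	0.21	0.21
FOCp	0.29	0.35
FP	0.30	0.38
INS	0.45	0.47
ITG	1.75	1.71
LPCi	0.98	0.96
LPCs	0.62	0.61
MPC	1.06	1.14
PH	0.62	0.63
PO	0.36	0.34
POGL	0.75	0.79
POGm	0.10	0.10
PMd	0.55	0.60
PMv	0.62	0.56
PreSMA	0.27	0.28
PRGL	0.76	0.82
PRGm/SMA	0.44	0.44
PRL	0.91	0.92
SC	0.09	0.10
STG	1.38	1.33
STPa	0.34	0.33
STPp	0.27	0.31
STRdli	1.06	1.15
STRdls	1.32	1.44
STRm	0.13	0.15
TP	0.43	0.39
VMO	0.78	0.83
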