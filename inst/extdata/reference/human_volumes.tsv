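pu	right_cm3	left_cm3
AGa	10.80	12.78
AGp	8.24	8.56
CALCi	1.77	2.04
CALCs	1.10	1.84
CGa_a	1.65	2.12
CGa_p	5.46	3.56
CGp	4.47	6.72
CN	4.52	4.86
COa	2.83	1.57
COp	1.34	2.89
F1La	5.09	2.17
F1Lm	4.75	5.70
F1Lp	8.91	6.16
F1m	2.13	1.82
F2a	6.67	8.69
F2m	8.38	9.37
F2p	4.61	2.98
F3a	5.08	4.71
F3o	3.87	4.42
F3orb	6.35	2.26
F3t	4.46	5.32
FMC	2.28	2.17
FO	2.79	5.02
FOCa	2.22	1.55
FOCL	6.23	3.74
FOCm	3.22	4.13
FOCp	2.60	4.07
FPL	6.47	7.36
FPm	4.85	2.23
H1	2.45	2.21
INSa	5.06	5.92
INSp	3.00	3.01
LG	5.17	5.10
OF	5.09	5.02
OLi	7.33	7.49
OLs	6.72	6.06
OP	19.03	9.04
PAC	4.82	5.44
PCN	14.21	13.31
PHa	2.86	3.08
PHp	1.94	2.59
PO	3.60	6.00
POGLi	4.51	5.09
POGLm	6.54	5.46
POGLs	3.97	3.66
POGm	3.41	2.57
PP	2.01	3.36
PreSMAi	3.39	4.54
PreSMAs	1.38	1.97
PRGLi	5.70	7.48
PRGLm	4.10	4.26
PRGLs	2.34	3.03
PRGm	2.97	3.13
PT	1.92	1.11
SC	2.91	3.19
SCALC	1.49	1.43
SGa	7.28	9.70
SGp	6.02	7.65
SMA	3.86	4.28
SPLa	9.70	11.99
SPLp	5.51	5.63
T1a	3.48	2.56
T1p	3.11	2.49
T2a	6.55	4.25
T2p	5.31	2.91
T3a	4.81	3.72
T3p	2.71	3.86
TFa	3.61	6.56
TFp	1.70	4.50
TO2	6.27	5.57
TO3	5.69	5.33
TOF	4.73	6.60
TP	7.87	10.19
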