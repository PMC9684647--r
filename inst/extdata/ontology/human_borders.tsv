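pu	ant	post	med_inf	lat_sup
AGa	CP E, im	CP F	ip	st, lo
AGp	CP F	PAL	ip	st, lo
CALCi	po	CP G	calc	CIL
CALCs	po	CP G	CSL	calc
CGa_a	ci	CP I	ci	ci
CGa_p	CP I	CP K	ca	ci
CGp	CP K	sp	ca, calc	ci, sp
CN	po	CP G	cun	HM
COa	CP O	CP R	cir	S45D
COp	CP R	CP P	cir	S45D
F1La	CP Q	CP I	HM	sf
F1Lm	CP I	CP O	HM	sf
F1Lp	CP O	prc	HM	sf
F1m	CP H	CP I	pa	HM
F2a	CP Q	CP I	sf	if
F2m	CP I	CP O	sf	if
F2p	CP O	prc	sf	if
F3a	CP Q	CP A	if	ahr
F3o	aar	prc	if	S45D
F3orb	CP Q	CP A	lorb	S45/ahr
F3t	CP A	aar	if	S45D
FMC	CP Q	CP I	pa	ol
FO	n/a	CP O	cir	S45D
FOCa	CP Q	torb	lorb	morb
FOCL	CP Q	circ	lorb	S45D/lorb
FOCm	CP Q	BF	morb	ol
FOCp	torb	BF, circ	morb	lorb
FPL	HM	CP Q	HM	HM
FPm	HM	CP H	HM	HM
H1	I45D	circ	ftr	He
INSa	circ	cei	circ	circ
INSp	cei	circ	circ	circ
LG	CP N	CP G	calc	co
OF	CP F	CP G	co	ot
OLi	CP F	CP G	ot	lo
OLs	PAL	CP G	HM	lo
OP	CP G	HM	HM	HM
PAC	pa	CP I, Ci	pa	pa
PCN	sp	po	calc	HM
PHa	CP B	CP M	co	hi
PHp	CP M	CP N	co	hi, calc
PO	CP P	CP D	cir	S45D
POGLi	ce	poc	S45D	IPOCL
POGLm	ce	poc	IPOCL	SPOCL
POGLs	ce	poc	SPOCL	HM
POGm	CP L	ci	ci	HM
PP	CP B	ftr	circ	I45D
PreSMAi	CP I	CP J	ci	pa
PreSMAs	CP I	CPJ	pa	HM
PRGLi	prc	ce	S45D	IPRCL
PRGLm	prc	ce	IPRCL	SPRCL
PRGLs	prc	ce	SPRCL	HM
PRGm	CP K	CP L	ci	HM
PT	He	CP D	circ	I45D
SC	CP I	BF, SEP	ol	ca
SCALC	poc	CP G	CSL	cun
SGa	poc	CP D	ip	S45D
SGp	CP D	CP E, im	ip	st
SMA	CP J	CP K	ci	HM
SPLa	poc	CP F	ip	HM
SPLp	CP F	PAL	ip	HM
T1a	CP B	CP C	I45D	st
T1p	CP C	CP D	I45D	st
T2a	CP B	CP C	st	it
T2p	CP C	CP D	st	it
T3a	CP B	CP C	it	ot
T3p	CP C	CP D	it	ot
TFa	CP B	CP C	ot	co
TFp	CP C	CP D	ot	co
TO2	CP D	CP F	st, lo	it
TO3	CP D	CP F	it	ot
TOF	CP D	CP F	ot	co
TP	HM	CP B	HM	HM
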