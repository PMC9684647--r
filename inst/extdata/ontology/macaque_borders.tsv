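pu	superior	inferior	anterior	posterior
CALCi	ccs	CIL	ccs (ant)	ccs (post)
CALCs	CSL	ccs	ccs (ant)	ccs (post)
CGa	cgs	ros, cas	CP A	CP C, CP G
CGp	cgs	cas, ccs	CP G, CP I	CP I, CP J, Pl a, sbps
COa	HM	crs	Ant end insula	CP F
COp	HM	crs	CP F	Post end insula
F1dli	ASL	prs	CP A	arc
F1dls	HM	ASL	CP A	CP B
F1dm	HM	cgs	CP A	CP B
F2	prs	HM	CP A	CP D
FMC	ros	olfs	CP A	CP C
FOCa	los	mos	CP A	tos
FOCL	HM	los	CP A	BF
FOCm	mos	olfs	CP A	BF
FOCp	los	mos	tos	BF
FP	HM	HM	HM	CP A
INS	crs	crs	Ant end insula	Post end insula
ITG	sts, Pl b	ots, rhs	CP E	CP J
LPCi	ips	ls, Pl c	CP H	IPS, Pl c
LPCs	cgs	itps	CP I	CP J
MPC	ips, cfs	CSL	sbps, CP J, CP I, Pl a	CP L
PH	HPC	ots, rhs	CP E, HM	CP I
PO	HM	crs, ls	CP H	ls (post end)
POGL	HM	lf	ce, CP F	CP H, CP I
POGm	HM	cgs	CP G	CP I
PMd	HM	arc, APL	CP B	CP M
PMv	APL	HM, ls	arc, CP D	CP M
PreSMA	HM	cgs	CP B	CP M
PRGL	HM	ls	CP M	ce, CP F
PRGm/SMA	HM	cgs	CP M	CP G
PRL	Pl c	iocs, Pl b	sts	lus, CP K
SC	cas	olfs	CP C	BF
STG	ls	sts, Pl c	CP E, M	sts
STPa	crs, ls	HM	CP E	1/2 STP
STPp	crs, ls	HM	1/2 STP	ls (post end)
STRdli	ecs	ios, CIL	lus, CP L, CP K, pos	HM
STRdls	sccs	ecs	lus, pos, CP L	HM
STRm	HM	CSL	CP L	HM
TP	HM	HM	HM	CP E
VMO	CIL	ios	CP J	CP L
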