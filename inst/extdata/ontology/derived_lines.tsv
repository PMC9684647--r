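id	species	name	construction
SPRCL	human	Superior precentral line	build_gyral_crest_lines
IPRCL	human	Inferior precentral line	build_gyral_crest_lines
SPOCL	human	Superior postcentral line	build_gyral_crest_lines
IPOCL	human	Inferior postcentral line	build_gyral_crest_lines
PAL	human	Parietal line	build_parietal_line
S45D	human	Superior 45 degree line of the Sylvian fissure	build_sylvian_opercular_lines
I45D	human	Inferior 45 degree line of the Sylvian fissure	build_sylvian_opercular_lines
CSL	both	Calcarine superior line	build_calcarine_lines
CIL	both	Calcarine inferior line	build_calcarine_lines
HM	both	Hemispheric margin	derive_hemispheric_margin
ASL	macaque	Superior arcuate line	build_macaque_frontal_lines
APL	macaque	Posterior arcuate line	build_macaque_frontal_lines
STP_MID	macaque	Supratemporal plane midline	build_stp_midline
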