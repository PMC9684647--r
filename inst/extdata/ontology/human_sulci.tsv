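abbrev	name	latin	other_names	neuronames_id	tna2_id	fipat_id	may_duplicate	provisional
aar	Anterior ascending ramus of lateral fissure	Ramus ascendens sulci lateralis	Anterior ascending limb of lateral fissure	68	5451	2005	FALSE	FALSE
ag	Angular sulcus			n.d.	n.d.	n.d.	FALSE	FALSE
ahr	Anterior horizontal ramus of lateral fissure	Ramus anterior sulci lateralis	Anterior ascending limb of lateral fissure	69	5449	2006	FALSE	FALSE
calc	Calcarine sulcus	Sulcus calcarinus		44	5486	2139	FALSE	FALSE
ca	Callosal sulcus	Sulcus corporis callosi	Sulcus of the corpus callosum	36	5439	2083	FALSE	FALSE
ce	Central sulcus	Sulcus centralis		48	5435	2088	FALSE	FALSE
cei	Central sulcus of the insula	Sulcus centralis insulae	Central insular sulcus	112	5505	2078	FALSE	FALSE
ci	Cingulate sulcus	Sulcus cinguli		43	5440	2084	FALSE	FALSE
cir	Circular sulcus of the insula	Sulcus circularis insulae	Limiting sulcus	51	5444	2079	FALSE	FALSE
co	Collateral sulcus	Sulcus collateralis		47	5442	2087	FALSE	FALSE
cun	Cuneal sulcus	n.d.	Superior sagittal sulcus of cuneus	n.d.	n.d.	n.d.	FALSE	FALSE
ftr	First transverse sulcus	Sulcus temporalis transversus anterior	Anterior transverse temporal sulcus	n.d.	n.d.	n.d.	FALSE	FALSE
He	Heschl's sulcus	Sulcus temporalis transversus posterior	Posterior transverse temporal sulcus	n.d.	n.d.	n.d.	TRUE	FALSE
hi	Hippocampal fissure	Sulcus hippocampalis		42	5522	2183	FALSE	FALSE
if	Inferior frontal sulcus	Sulcus frontalis inferior		63	5453	2018	FALSE	FALSE
it	Inferior temporal sulcus	Sulcus temporalis inferior		130	5496	2072	FALSE	FALSE
im	Intermediate sulcus of Jensen	Sulcus intermedius primus	Primary intermediate sulcus	2382	n.d.	n.d.	FALSE	FALSE
ip	Intraparietal sulcus	Sulcus intraparietalis		97	5475	2037	FALSE	FALSE
lo	Lateral occipital sulcus	n.d.		143	n.d.	n.d.	FALSE	FALSE
lorb	Lateral orbital sulcus	Sulcus orbitalis lateralis		81	n.d.	2111	TRUE	FALSE
ma	Marginal ramus of the cingulate sulcus			n.d.	n.d.	n.d.	FALSE	TRUE
morb	Medial orbital sulcus	Sulcus orbitalis medialis		82	n.d.	2113	FALSE	FALSE
ot	Occipitotemporal sulcus	Sulcus occipitotemporalis		55	5438	2147	FALSE	FALSE
ol	Olfactory sulcus	Sulcus olfactorius		78	5463	2115	FALSE	FALSE
pa	Paracingulate sulcus	n.d.		2399	n.d.	n.d.	FALSE	FALSE
po	Parietooccipital sulcus	Sulcus parietooccipitalis		52	5437	2007	FALSE	FALSE
pcs	Postcentral sulcus	Sulcus postcentralis		99	5740	2035	FALSE	FALSE
par	Posterior ascending ramus of the Sylvian fissure			n.d.	n.d.	n.d.	FALSE	TRUE
phr	Posterior horizontal ramus of the Sylvian fissure			n.d.	n.d.	n.d.	FALSE	TRUE
prs	Precentral sulcus	Sulcus precentralis		3474	5457	2027	FALSE	FALSE
sp	Subparietal sulcus	Sulcus subparietalis	Splenial sulcus	102	5441	2135	FALSE	FALSE
sf	Superior frontal sulcus	Sulcus frontalis superior		61	5455	2032	FALSE	FALSE
st	Superior temporal sulcus	Sulcus temporalis superior		129	5494	2070	FALSE	FALSE
torb	Transverse orbital sulcus	Sulcus orbitalis transversus		80	n.d.	2112	FALSE	FALSE
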