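abbrev	name	latin	other_names	neuronames_id	tna2_id	fipat_id	may_duplicate	provisional
arc	Arcuate sulcus	Sulcus arcuatus		2379	n.d.	n.d.	FALSE	FALSE
ccs	Calcarine sulcus	Sulcus calcarinus		44	n.d.	n.d.	FALSE	FALSE
cas	Callosal sulcus	Sulcus corporis callosi		36	n.d.	n.d.	FALSE	FALSE
ce	Central sulcus	Sulcus centralis		48	n.d.	n.d.	FALSE	FALSE
cgs	Cingulate sulcus	Sulcus cinguli		43	n.d.	n.d.	FALSE	FALSE
ecs	External calcarine sulcus			146	n.d.	n.d.	FALSE	FALSE
iccs	Inferior calcarine sulcus			148	n.d.	n.d.	FALSE	FALSE
iocs	Inferior occipital sulcus			144	n.d.	n.d.	FALSE	FALSE
itps	Intraparietal sulcus	Sulcus intraparietalis		97	n.d.	n.d.	FALSE	FALSE
lf	Lateral fissure	Sulcus lateralis		49	n.d.	n.d.	FALSE	FALSE
los	Lateral orbital sulcus			81	n.d.	n.d.	FALSE	FALSE
crs	Limiting sulcus of the insula	Sulcus circularis insulae		51	n.d.	n.d.	FALSE	FALSE
lus	Lunate sulcus			150	n.d.	n.d.	FALSE	FALSE
ms	Marginal sulcus			98	n.d.	n.d.	FALSE	FALSE
mos	Medial orbital sulcus			82	n.d.	n.d.	FALSE	FALSE
ots	Occipitotemporal sulcus			55	n.d.	n.d.	FALSE	FALSE
olfs	Olfactory sulcus	Sulcus olfactorius		78	n.d.	n.d.	FALSE	FALSE
pos	Parietooccipital sulcus			52	n.d.	n.d.	FALSE	FALSE
prs	Principal sulcus	Sulcus principalis		66	n.d.	n.d.	FALSE	FALSE
rhs	Rhinal sulcus	Sulcus rhinalis		41	n.d.	n.d.	FALSE	FALSE
ros	Rostral sulcus			76	n.d.	n.d.	FALSE	FALSE
sbps	Subparietal sulcus			102	n.d.	n.d.	FALSE	FALSE
sccs	Superior calcarine sulcus			147	n.d.	n.d.	FALSE	FALSE
sts	Superior temporal sulcus			129	n.d.	n.d.	FALSE	FALSE
tos	Transverse orbital sulcus			80	n.d.	n.d.	FALSE	FALSE
hpc	Hippocampal sulcus	Sulcus hippocampalis		42	n.d.	n.d.	FALSE	TRUE
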