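id	kind	defining_event
BF	surface-landmark	Orbitofrontal cortex, posterior limit
CP A	coronal-plane	Anterior horizontal ramus of Sylvian fissure, anterior limit
CP B	coronal-plane	Isthmus of temporal and frontal lobes
CP C	coronal-plane	Sulcus of Heschl, anterior limit
CP D	coronal-plane	Sylvian fissure, posterior limit
CP E	coronal-plane	Intermediate sulcus of Jensen, inferior limit
CP F	coronal-plane	Opercularization of the intraparietal sulcus
CP G	coronal-plane	Cuneal sulcus, posterior limit
CP H	coronal-plane	Paracingulate gyrus, anterior limit
CP I	coronal-plane	Corpus callosum, anterior limit
CP J	coronal-plane	Decussation of anterior commissure
CP K	coronal-plane	Precentral sulcus junction with hemispheric margin
CP L	coronal-plane	Central sulcus junction with hemispheric margin
CP M	coronal-plane	Lateral geniculate nucleus
CP N	coronal-plane	Calcarine sulcus, anterior limit
CP O	coronal-plane	Precentral sulcus junction with Sylvian fissure
CP P	coronal-plane	Postcentral sulcus junction with Sylvian fissure
CP Q	coronal-plane	Olfactory sulcus, anterior limit
CP R	coronal-plane	Central sulcus junction with Sylvian fissure
SEP	surface-landmark	Subcallosal cortex, posterior limit
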