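id	kind	defining_event
BF	surface-landmark	Orbitofrontal cortex, posterior limit
CP A	coronal-plane	Rostral sulcus, anterior limit
CP B	coronal-plane	Superior ramus of arcuate sulcus, anterior limit
CP C	coronal-plane	Corpus callosum, anterior limit
CP D	coronal-plane	Inferior ramus of arcuate sulcus, inferior limit
CP E	coronal-plane	Isthmus of temporal and frontal lobes
CP F	coronal-plane	Central sulcus junction with Sylvian fissure
CP G	coronal-plane	Central sulcus junction with hemispheric margin
CP H	coronal-plane	Intraparietal sulcus, anterior limit
CP I	coronal-plane	Calcarine sulcus, anterior limit
CP J	coronal-plane	Inferior occipital sulcus, anterior limit
CP K	coronal-plane	Lunate sulcus, inferior limit
CP L	coronal-plane	Parietooccipital sulcus, inferior limit
CP M	coronal-plane	Decussation of anterior commissure
Pl a	auxiliary-plane	Between superior limit of subparietal sulcus and coronal plane I
Pl b	auxiliary-plane	Horizontal line from anterior limit of inferior occipital sulcus to superior temporal sulcus
Pl c	auxiliary-plane	Between superior limit of Sylvian fissure, and confluence of lunate and intraparietal sulci
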