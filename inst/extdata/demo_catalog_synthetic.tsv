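accession	organism	phylum	enzyme_class	polymers	category
SYN_MCO_01	synthetic isolate 1	Actinobacteria	multicopper oxidase	PE	CC_BACKBONE
SYN_MCO_02	synthetic isolate 1	Actinobacteria	multicopper oxidase	PE	CC_BACKBONE
SYN_ALKB_01	synthetic isolate 2	Actinobacteria	alkane 1-monooxygenase	PE	CC_BACKBONE
SYN_P450_01	synthetic isolate 3	Proteobacteria	cytochrome P450 hydroxylase	PE	CC_BACKBONE
SYN_CUT_01	synthetic isolate 4	Actinobacteria	cutinase	PET	HETEROATOMIC
SYN_PUE_01	synthetic isolate 5	Firmicutes	PU esterase	PU,PET	HETEROATOMIC
SYN_PHBD_01	synthetic isolate 6	Proteobacteria	PHB-depolymerase	PHB,PHBV	POLYESTER
SYN_CARB_01	synthetic isolate 7	Actinobacteria	carboxylesterase	PBAT,PLA,PCL	POLYESTER
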