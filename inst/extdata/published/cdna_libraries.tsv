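library_id	cultivar	tissue	library_type	n5	n3
PFTP2	PI161375	fruit	FULL_LENGTH	12673	547
SFTP2	Piel de Sapo T-111	fruit	FULL_LENGTH	3630	139
VFTP2	Vedrantais	fruit	FULL_LENGTH	3621	149
DFTP2	Dulce	fruit	FULL_LENGTH	3549	70
VFLP2	Vedrantais	flower	FULL_LENGTH	19261	638
PFLP2	PI161375	flower	FULL_LENGTH	3548	62
DFLP2	Dulce	flower	FULL_LENGTH	3411	126
SFLP2	Piel de Sapo T-111	flower	FULL_LENGTH	320	0
MNFG2	Piel de Sapo T-111	leaf	FULL_LENGTH	7776	295
MNRP2	Piel de Sapo T-111	root	FULL_LENGTH	7953	297
MNCP2	Piel de Sapo T-111	cotyledon	FULL_LENGTH	3454	58
CM-DEa	Dulce	callus	STANDARD	5485	0
CM-PEa	PI161375	callus	STANDARD	5527	0
CM-TEa	Piel de Sapo	callus	STANDARD	5700	0
CM-VEa	Vedrantais	callus	STANDARD	5467	0
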