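HYPOXIA_21	package-curated representative 21-gene hypoxia signature (synthetic stand-in for the study gene list)	VEGFA	ANGPTL4	LGALS3	CA9	SLC2A1	LDHA	PGK1	HK2	ADM	NDRG1	ENO1	PDK1	EGLN3	P4HA1	P4HA2	ALDOA	BNIP3	SERPINE1	PLOD1	PFKFB3	DDIT4
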