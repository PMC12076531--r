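Condition	SampleVolume	ProteinConcentration	AmountMS	CellsPerML	TotalCultureVolume	ProteinSRM	fmolSRM	Enrichment	EnrichmentMode	StdDilution	StdVolume
Cond1_t0	2.31	2.99	9.67	4.54	7.54	TNAMLN	4.44	FALSE
Cond2_t1	2.5	0.2	4.1	5.13	2.62	AJFVYC	4.85	TRUE	Concentration	10	10
Cond3_t2	7.38	6.56	2.77	3.66	3.8	BYEKSC	9.71	TRUE	Enrichment	2	10
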