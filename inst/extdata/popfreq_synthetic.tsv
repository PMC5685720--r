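chrom	pos	ref	alt	af_1000g_all	af_1000g_eur	af_esp_eur
JAK2syn	638	G	A	0.12	0.1	0.14
JAK2syn	330	C	T	0.001	0.002	0
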