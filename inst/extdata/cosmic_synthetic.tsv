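chrom	pos	ref	alt	cosmic_id	protein
JAK2syn	325	A	G	COSS1	p.R683G
JAK2syn	326	G	C	COSS2	p.R683T
JAK2syn	918	G	A	COSS3	p.R867Q
JAK2syn	1211	G	A	COSS4	p.R923H
JAK2syn	606	G	A	COSS5	p.D760N
JAK2syn	942	A	G	COSS6	p.E875G
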