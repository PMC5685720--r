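JAK2syn	300	375	exon16
JAK2syn	575	695	exon20
JAK2syn	895	985	exon21
JAK2syn	1185	1305	exon23
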