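class	pattern
# ICE signature-gene keyword screen; first match wins.
integration_excision	integrase
integration_excision	excisionase
integration_excision	site-specific recombinase
integration_excision	tyrosine recombinase
replication	helicase
replication	primase
replication	dna polymerase
replication	replication protein
replication	replisome
conjugation	conjugal transfer
conjugation	conjugative
conjugation	trbl
conjugation	parb
conjugation	partitioning protein
conjugation	secretion
conjugation	single-stranded dna-binding
conjugation	mobilization
conjugation	relaxase
conjugation	ftsk
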