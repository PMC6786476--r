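prefix	gene_class
psa	photosystem
psb	photosystem
pet	cytochrome_b6f
atp	atp_synthase
ndh	ndh
rbc	rubisco
chl	chl
rpo	rpo
rpl	ribosomal_protein
rps	ribosomal_protein
trn	trna
rrn	rrna
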