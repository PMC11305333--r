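# Synthetic reconstruction of the pan-genus PL loss-of-function allele survey:
# 16 distinct deleterious alleles; shared_group marks identical alleles
# observed in two species (dagger/ddagger/section). Species names outside the
# three mapped crop species and the two documented shared-allele partners, and
# all position keys, are synthetic placeholders.
species	gene	effect_class	position	shared_group	source
S. melongena	PL	splice_donor	intron3+1G>A	.	mapping
S. melongena	PL	large_exonic_deletion	exon6_del474	.	mapping
S. aethiopicum	PL	frameshift	c.1022insT	.	mapping
S. macrocarpon	PL	splice_donor	intron1+1G>T	dagger	mapping
S. donianum	PL	splice_donor	intron1+1G>T	dagger	survey
S. lanzae	PL	splice_acceptor	intron4-1G>C	ddagger	survey
S. stramoniifolium	PL	splice_acceptor	intron4-1G>C	ddagger	survey
Solanum sp. S01	PL	stop_gained	c.304C>T	section	survey
Solanum sp. S02	PL	stop_gained	c.304C>T	section	survey
Solanum sp. S03	PL	frameshift	c.211delA	.	survey
Solanum sp. S04	PL	frameshift	c.587_588insGA	.	survey
Solanum sp. S05	PL	splice_donor	intron2+2T>C	.	survey
Solanum sp. S06	PL	stop_gained	c.790G>T	.	survey
Solanum sp. S07	PL	large_exonic_deletion	exon2_del88	.	survey
Solanum sp. S08	PL	start_lost	c.2T>C	.	survey
Solanum sp. S09	PL	splice_acceptor	intron5-2A>G	.	survey
Solanum sp. S10	PL	frameshift	c.1306delG	.	survey
Solanum sp. S11	PL	stop_gained	c.922C>T	.	survey
Solanum sp. S12	PL	splice_donor	intron6+1G>A	.	survey
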