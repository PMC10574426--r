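receptor	ligand	affinity
MAPK14	Luteolin	-8.194
MAPK1	Involucratin	-9.624
RELA	Involucratin	-8.904
TNF	Xuelianlactone	-10.01
MAPK8	Involucratin	-9.794
IL6	Quercetin	-7.562
IL1B	Flazin	-7.475
CHUK	Flazin	-7.266
IKBKB	Quercetin	-7.174
NFKBIA	Luteolin	-8.604
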