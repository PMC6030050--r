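library	taxon	rank	count	printed_category
oak_honeydew	Metcalfa pruinosa	species	6982	High
honeydew_trentino	Metcalfa pruinosa	species	6300	High
honeydew_veneto	Metcalfa pruinosa	species	4392	High
fir_emilia	Cinara pectinatae	species	2097	High
fir_emilia	Metcalfa pruinosa	species	1	Low
fir_piedmont	Metcalfa pruinosa	species	1944	High
fir_piedmont	Cinara pectinatae	species	1899	High
fir_piedmont	Issus muscaeformis	species	116	Low
fir_piedmont	Cinara terminalis	species	24	Low
fir_piedmont	Aphis cisticola	species	12	Low
fir_piedmont	Schizaphis graminum	species	5	Low
fir_piedmont	Mindarus abietinus	species	4	Low
fir_piedmont	Cinara curvipes	species	1	Low
fir_piedmont	Cinara oregonensis	species	1	Low
fir_piedmont	Kaltenbachiella spinosa	species	1	Low
fir_piedmont	Rhopalosiphum maidis	species	1	Low
chestnut	Metcalfa pruinosa	species	16572	High
apple	Metcalfa pruinosa	species	657	High
apple	Rhopalosiphum insertum	species	148	Medium
apple	Myzus persicae	species	77	Medium
apple	Cavariella aegopodii	species	45	Low
apple	Aphis gossypii	species	38	Low
apple	Therioaphis trifolii	species	14	Low
apple	Acyrthosiphon pisum	species	10	Low
apple	Aphis craccivora	species	10	Low
apple	Myzocallis castanicola	species	6	Low
apple	Pleotrichophorus sp.	genus	1	Low
apple	Cinara sp.	genus	2	Low
apple	Aphis cytisorum	species	1	Low
apple	Schizaphis graminum	species	1	Low
apple	Brachycaudus salicinae	species	1	Low
linden	Metcalfa pruinosa	species	2026	High
linden	Aphis craccivora	species	219	Medium
linden	Issus muscaeformis	species	172	Medium
linden	Eucallipterus tiliae	species	70	Low
linden	Aphididae spp.	family	15	Low
linden	Thelaxes suberi	species	13	Low
linden	Cinara cedri	species	10	Low
linden	Illinoia liriodendri	species	2	Low
linden	Aphis craccae	species	2	Low
linden	Brachycaudus populi	species	1	Low
acacia	Metcalfa pruinosa	species	2594	High
acacia	Hyalopterus pruni	species	56	Low
acacia	Aphis gossypii	species	19	Low
acacia	Acyrthosiphon caraganae	species	10	Low
acacia	Chaitophorus leucomelas	species	6	Low
acacia	Dysaphis plantaginea	species	1	Low
eucalyptus_calabria	Metcalfa pruinosa	species	4127	High
eucalyptus_calabria	Cinara cedri	species	358	Medium
eucalyptus_calabria	Aphis gossypii	species	172	Low
eucalyptus_calabria	Aphis taraxacicola	species	70	Low
eucalyptus_calabria	Cinara tujafilina	species	70	Low
eucalyptus_calabria	Brachycaudus cardui	species	56	Low
eucalyptus_calabria	Aphis spiraecola	species	34	Low
eucalyptus_calabria	Aphis craccivora	species	9	Low
eucalyptus_calabria	Aphis glycines	species	1	Low
eucalyptus_calabria	Brachycaudus persicae	species	1	Low
eucalyptus_calabria	Aphis egomae	species	1	Low
eucalyptus_calabria	Cervaphis rappardi	species	1	Low
eucalyptus_sicily	Metcalfa pruinosa	species	2849	High
eucalyptus_sicily	Myzus persicae	species	32	Low
eucalyptus_sicily	Acyrthosiphon pisum	species	18	Low
eucalyptus_sicily	Issus muscaeformis	species	7	Low
eucalyptus_sicily	Aphis gossypii	species	1	Low
corsica_polyfloral	Metcalfa pruinosa	species	8675	High
corsica_polyfloral	Aphis gossypii	species	145	Low
corsica_polyfloral	Aphis taraxacicola	species	57	Low
corsica_polyfloral	Thelaxes suberi	species	23	Low
corsica_polyfloral	Aphis ruborum	species	10	Low
corsica_polyfloral	Issus coleoptratus	species	4	Low
corsica_polyfloral	Dysaphis lappae	species	3	Low
corsica_polyfloral	Aphis spiraecola	species	2	Low
corsica_polyfloral	Acyrthosiphon malvae	species	2	Low
corsica_polyfloral	Myzus persicae	species	2	Low
corsica_polyfloral	Aphis glycines	species	2	Low
corsica_polyfloral	Aphis craccivora	species	2	Low
corsica_polyfloral	Cavariella aegopodii	species	2	Low
corsica_polyfloral	Aulacorthum solani	species	1	Low
corsica_polyfloral	Chaitophorus leucomelas	species	1	Low
corsica_polyfloral	Issus muscaeformis	species	1	Low
corsica_polyfloral	Hoplocallis picta	species	1	Low
eastern_europe_polyfloral	Metcalfa pruinosa	species	22856	High
eastern_europe_polyfloral	Aulacorthum solani	species	90	Low
eastern_europe_polyfloral	Pemphigus bursarius	species	46	Low
eastern_europe_polyfloral	Eucallipterus tiliae	species	4	Low
eastern_europe_polyfloral	Hyperomyzus carduellinus	species	1	Low
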