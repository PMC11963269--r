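# Structural characteristics of 63 published Retand PRARE cluster consensus elements
# (literature-derived reference table; sizes in bp are per-cluster averages).
# trp28_short_orf: TRP28 domain present but only in an ORF shorter than 600 nt.
# other_domains: Smc = chromosome segregation ATPase; polIII = DNA polymerase III
# gamma/tau; DNAtopo2 = DNA topoisomerase 2; RecomInh = recombination inhibitor; TolA.
clade	cluster	copy_number	ltr_bp	internal_bp	pol3ltr_bp	gag	ap	rh	int	trp28	trp28_short_orf	other_domains	tandem_arrays
Liliopsida_1	Alopecurus_myosuroides_7c	26	477	9671	5427	NO	YES	YES	YES	YES	FALSE	.	0
Liliopsida_1	Alopecurus_myosuroides_7b	23	481	9685	5433	NO	YES	YES	YES	YES	FALSE	.	0
Liliopsida_1	Alopecurus_myosuroides_7a	13	479	9680	5428	NO	YES	YES	YES	YES	FALSE	.	0
Liliopsida_1	Alopecurus_myosuroides_7j	180	454	9480	5305	NO	YES	YES	YES	YES	FALSE	.	0
Liliopsida_1	Alopecurus_myosuroides_7i	52	454	9581	5279	NO	YES	YES	YES	YES	FALSE	.	0
Liliopsida_1	Aegilops_umbellulata_1	3	504	12140	5663	YES	YES	YES	YES	YES	FALSE	.	1
Liliopsida_1	Secale_cereale_1	10	506	12869	6091	YES	YES	YES	YES	YES	FALSE	.	1
Liliopsida_1	Secale_cereale_2	26	507	12726	6153	YES	YES	YES	YES	YES	FALSE	.	1
Liliopsida_1	Avena_atlantica_1	37	491	11237	4743	YES	YES	YES	YES	YES	FALSE	DNAtopo2	1
Liliopsida_1	Alopecurus_myosuroides_3a	46	576	10798	3906	YES	NO	YES	YES	YES	FALSE	.	0
Liliopsida_1	Alopecurus_myosuroides_3b	43	577	8734	4079	YES	YES	NO	NO	YES	FALSE	.	0
Liliopsida_1	Alopecurus_myosuroides_2	55	564	8734	4102	YES	YES	NO	NO	YES	FALSE	.	0
Liliopsida_1	Triticum_aestivum_10	10	528	11996	5828	YES	YES	YES	YES	YES	FALSE	.	1
Liliopsida_1	Poa_annua_1b	10	424	12250	5501	YES	YES	YES	YES	YES	FALSE	.	2
Liliopsida_1	Poa_annua_1a	15	439	12029	5301	YES	YES	YES	YES	YES	FALSE	.	2
Liliopsida_1	Alopecurus_myosuroides_5c	133	491	11821	5491	YES	YES	YES	YES	YES	FALSE	.	0
Liliopsida_1	Alopecurus_myosuroides_5b	15	493	11834	5474	YES	NO	YES	YES	YES	FALSE	.	0
Liliopsida_1	Saccharum_spontaneum_1a	10	1065	12304	5854	YES	YES	YES	YES	YES	FALSE	polIII	0
Liliopsida_1	Oryza_rufipogon_2	18	440	10428	4282	YES	YES	YES	YES	YES	FALSE	.	0
Liliopsida_2	Oryza_rufipogon_1d	35	1077	10727	4484	YES	YES	YES	YES	YES	FALSE	Smc	0
Liliopsida_2	Oryza_rufipogon_1c	61	1174	10703	4483	YES	YES	YES	YES	YES	FALSE	Smc	0
Liliopsida_2	Secale_cereale_5b	21	947	11752	5367	YES	YES	YES	YES	YES	FALSE	Smc,polIII	0
Liliopsida_2	Secale_cereale_5a	65	954	11775	5359	YES	YES	YES	YES	YES	FALSE	Smc,polIII	2
Liliopsida_2	Poa_annua_4b	21	1031	10962	4981	YES	YES	YES	YES	YES	FALSE	Smc,polIII	0
Liliopsida_2	Poa_annua_4a	24	1079	10861	4914	YES	YES	YES	YES	YES	FALSE	.	0
Liliopsida_3	Zea_mays_2	12	585	8245	4200	NO	YES	YES	YES	YES	FALSE	.	0
Liliopsida_3	Zea_mays_1	21	587	8365	4313	NO	NO	YES	YES	YES	FALSE	.	1
Eudicot_1	Artemisia_tridentata_2a	63	488	9588	3868	YES	YES	YES	YES	YES	FALSE	.	0
Eudicot_1	Artemisia_tridentata_1	42	488	9581	3899	YES	YES	YES	YES	YES	FALSE	.	0
Eudicot_1	Artemisia_argyi_1	81	496	9362	3665	YES	YES	YES	YES	YES	FALSE	.	0
Eudicot_1	Glebionis_coronaria_2b	13	571	9588	4035	YES	NO	YES	YES	YES	FALSE	.	0
Eudicot_1	Glebionis_coronaria_2a	41	581	9843	4108	YES	NO	YES	YES	YES	FALSE	.	0
Eudicot_1	Helianthus_annuus_3a	23	880	10274	4549	YES	YES	YES	YES	YES	FALSE	.	1
Eudicot_1	Helianthus_annuus_2	15	806	11456	5899	YES	YES	YES	YES	YES	FALSE	TolA	0
Eudicot_1	Salvia_splendens_1	23	597	9719	4234	YES	YES	YES	YES	YES	FALSE	.	1
Eudicot_2	Medicago_ruthenica_1	19	315	7380	3888	NO	NO	YES	YES	YES	FALSE	.	0
Eudicot_2	Lotus_japonicus_1	47	378	8780	3281	YES	YES	YES	YES	YES	FALSE	.	0
Eudicot_2	Comarum_palustre_1	63	483	9994	4340	YES	YES	YES	YES	YES	FALSE	.	3
Eudicot_2	Spinacia_oleracea_1	54	425	10719	4850	YES	YES	YES	YES	YES	FALSE	.	1
Eudicot_2	Ballota_nigra_5a	28	775	10294	4118	YES	YES	YES	YES	YES	FALSE	.	0
Eudicot_2	Ballota_nigra_3	28	685	10371	4252	YES	YES	YES	YES	YES	FALSE	.	0
Eudicot_2	Ballota_nigra_2a	19	737	10519	4282	YES	YES	YES	YES	YES	FALSE	Smc	0
Eudicot_2	Ballota_nigra_1	12	696	9557	3609	YES	YES	YES	YES	YES	FALSE	RecomInh	1
Eudicot_2	Apium_graveolens_1b	24	569	9357	3801	YES	YES	YES	YES	YES	FALSE	.	2
Eudicot_2	Apium_graveolens_1a	41	548	9753	4121	YES	YES	YES	YES	YES	FALSE	.	2
Eudicot_2	Apium_graveolens_2a	10	570	9626	3997	YES	YES	YES	YES	YES	FALSE	.	3
Eudicot_2	Heracleum_sosnowskyi_2a	16	504	10937	3492	YES	YES	YES	YES	YES	FALSE	.	1
Eudicot_2	Heracleum_sosnowskyi_1	38	504	9198	3459	YES	YES	YES	YES	YES	FALSE	.	2
Eudicot_2	Chamaenerion_angustifolium_2	171	664	10051	4522	YES	YES	YES	YES	YES	FALSE	.	1
Eudicot_2	Sambucus_nigra_4	76	586	10964	4895	YES	YES	YES	YES	YES	TRUE	.	1
Eudicot_2	Sambucus_nigra_2	29	586	10938	4954	YES	YES	YES	YES	YES	TRUE	.	1
Eudicot_2	Sambucus_nigra_3	68	586	10943	4953	YES	YES	YES	YES	YES	TRUE	.	1
Eudicot_2	Sambucus_nigra_6	39	857	10861	4771	YES	YES	YES	YES	YES	FALSE	.	1
Eudicot_2	Camellia_oleifera_2	13	551	10377	4812	YES	YES	YES	YES	YES	FALSE	Smc	2
Eudicot_2	Nyssa_sinensis_1	15	627	10468	4582	YES	YES	YES	YES	YES	FALSE	.	2
Eudicot_2	Dimocarpus_longan_1	10	713	9540	3682	YES	YES	YES	YES	YES	FALSE	Smc	0
Eudicot_2	Camellia_sinensis_4	18	824	10483	4472	YES	YES	YES	YES	YES	TRUE	.	1
Eudicot_2	Camellia_oleifera_1	23	584	9983	4290	YES	NO	YES	YES	YES	TRUE	.	1
Eudicot_2	Centaurea_solstitialis_2a	58	900	8485	2933	YES	YES	YES	YES	YES	FALSE	.	1
Eudicot_2	Helianthus_annuus_5	121	719	9313	3343	YES	YES	YES	YES	NO	FALSE	.	2
Eudicot_2	Helianthus_annuus_4	71	720	9310	3327	YES	YES	YES	YES	NO	FALSE	.	2
Liliopsida_Eudicot	Rhynchospora_pubera_3	12	432	11818	5552	YES	YES	YES	YES	YES	FALSE	.	3
Liliopsida_Eudicot	Linaria_vulgaris_1	22	1194	12114	6556	YES	YES	YES	YES	YES	FALSE	.	0
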