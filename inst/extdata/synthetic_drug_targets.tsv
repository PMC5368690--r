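drug_id	drug_name	target_gene	approved_flag	atc_code
DB00001	synthadrug01	GENE00004	TRUE	N05C
DB00002	synthadrug02	GENE00004	TRUE	N05C
DB00003	synthadrug03	GENE00004	TRUE	N05C
DB00004	synthadrug04	GENE00004	TRUE	N05C
DB00005	synthadrug05	GENE00004	TRUE	N05C
DB00006	synthadrug06	GENE00004	TRUE	N05C
DB00007	synthadrug07	GENE00004	TRUE	N05C
DB00008	synthadrug08	GENE00004	TRUE	N05C
DB00009	synthadrug09	GENE00004	TRUE	N05C
DB00010	synthadrug10	GENE00004	TRUE	N05C
DB00011	synthadrug11	GENE00004	TRUE	N05C
DB00012	synthadrug12	GENE00004	TRUE	N05C
DB00013	synthadrug13	GENE00004	TRUE	N05C
DB00014	synthadrug14	GENE00004	TRUE	N05C
DB00015	synthadrug15	GENE00004	TRUE	N05C
DB00016	synthadrug16	GENE00004	TRUE	N05C
DB00017	synthadrug17	GENE00004	TRUE	N05C
DB00018	synthadrug18	GENE00004	TRUE	N05C
DB00019	synthadrug19	GENE00004	TRUE	N05C
DB00020	synthadrug20	GENE00004	TRUE	N05C
DB00021	synthadrug21	GENE00004	TRUE	N05C
DB00022	synthadrug22	GENE00004	TRUE	N05C
DB00023	synthadrug23	GENE00004	TRUE	N05C
DB00024	synthadrug24	GENE00004	TRUE	N05C
DB00025	synthadrug25	GENE00004	TRUE	N05C
DB00026	synthadrug26	GENE00004	TRUE	N05C
DB00027	synthadrug27	GENE00004	TRUE	N05C
DB00028	synthadrug28	GENE00004	TRUE	N05C
DB00029	synthadrug29	GENE00004	TRUE	N05C
DB00030	synthadrug30	GENE00004	TRUE	N05C
DB00031	synthadrug31	GENE00004	TRUE	N05C
DB00032	synthadrug32	GENE00004	TRUE	N05C
DB00033	synthadrug33	GENE00004	TRUE	N05C
DB00034	synthadrug34	GENE00004	TRUE	N05C
DB00035	synthadrug35	GENE00004	TRUE	N05C
DB00036	synthadrug36	GENE00004	TRUE	N05C
DB00037	synthadrug37	GENE00004	TRUE	N05C
DB00038	synthadrug38	GENE00004	TRUE	N05C
DB00039	synthadrug39	GENE00004	TRUE	N05C
DB00040	synthadrug40	GENE00004	TRUE	N05C
DB00041	synthadrug41	GENE00004	TRUE	L01XX
DB00042	synthbdrug01	GENE00005	TRUE	L01AA
DB00043	synthbdrug02	GENE00005	FALSE	L01AA
DB00044	synthbdrug03	GENE00018	TRUE	C07AB
DB00045	synthbdrug04	GENE00025	TRUE	N02BE
DB00046	synthbdrug05	GENE00031	TRUE	L01BC
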