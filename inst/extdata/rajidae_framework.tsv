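species	basin	subarea	n	nh	h	h_sd	pi	pi_sd	source
Amblyraja hyperborea	Atlantic	Northeast Atlantic	10	2	0.2	NA	0.0003	NA	ref060
Amblyraja hyperborea	Atlantic	Canada	30	7	0.582	NA	0.0014	NA	ref061
Amblyraja jenseni	Atlantic	Canada	20	5	0.663	NA	0.0017	NA	ref061
Amblyraja radiata	Atlantic	Northeast Atlantic	10	8	0.956	NA	0.005	NA	ref060
Amblyraja radiata	Atlantic	Canada	38	20	0.939	NA	0.0071	NA	ref061
Bathyraja spinicauda	Atlantic	Canada	29	4	0.253	NA	0.001	NA	ref061
Dipturus nidarosiensis	Atlantic	Northeast Atlantic	10	2	0.556	NA	0.0009	NA	ref060
Dipturus nidarosiensis	Mediterranean	Sardinia	49	3	0.119	0.062	0.0002	0.0003	ref062
Dipturus oxyrinchus	Mediterranean	Malta	10	2	0.2	0.154	0.0003	0.0005	ref063
Dipturus oxyrinchus	Mediterranean	Sardinia	175	11	0.253	0.044	0.0005	0.0001	ref064
Dipturus oxyrinchus	Atlantic	Northeast Atlantic	10	1	0	NA	0	NA	ref060
Dipturus oxyrinchus	Mediterranean	Ionian Sea	14	1	0	NA	0	NA	ref065
Leucoraja erinacea	Atlantic	Canada	67	30	0.88	NA	0.0049	NA	ref061
Leucoraja ocellata	Atlantic	Canada	35	16	0.93	NA	0.0033	NA	ref061
Malacoraja senta	Atlantic	Canada	44	7	0.686	NA	0.0017	NA	ref061
Raja asterias	Mediterranean	North Africa	30	6	0.559	0.088	0.0186	0.0163	ref066
Raja asterias	Mediterranean	Sardinia + Tyrrhenian Sea	138	7	0.1287	0.0663	0.0039	0.0064	ref066
Raja asterias	Mediterranean	Sicilian Strait + West Ionian	19	6	0.58	0.1685	0.046	NA	ref066
Raja asterias	Mediterranean	Adriatic Sea	78	8	0.482	0.1265	0.015	0.0147	ref066
Raja brachyura	Mediterranean	Sardinia	11	2	0.3273	0.1533	0.0005	0.0006	ref065
Raja clavata	Mediterranean	Malta	25	2	0.08	0.07	0.0001	0.0003	ref063
Raja clavata	Atlantic	Northeast Atlantic	10	1	0	NA	0	NA	ref060
Raja clavata	Mediterranean	Adriatic Sea	40	2	0.05	0.0469	0.0001	0.0002	ref065
Raja miraletus	Atlantic	South Africa	41	9	0.691	0.063	0.0019	0.0035	ref067
Raja miraletus	Atlantic	Angola	27	10	0.858	0.041	0.0254	0.0196	ref067
Raja miraletus	Atlantic	Portugal	10	1	0	NA	0	NA	ref067
Raja miraletus	Mediterranean	Sardinia	11	1	0	NA	0	NA	ref067
Raja miraletus	Mediterranean	North Tyrrhenian	28	2	0.701	0.065	0.0001	0.0005	ref067
Raja miraletus	Mediterranean	Algerian Coasts	17	4	0.419	0.141	0.0014	0.0022	ref067
Raja miraletus	Mediterranean	Sicilian Strait	45	6	0.711	0.039	0.0029	0.0026	ref067
Raja miraletus	Mediterranean	Adriatic Sea	87	7	0.486	0.051	0.001	0.0023	ref067
Raja miraletus	Mediterranean	Israel	14	2	0.527	0.064	0.001	0.0006	ref067
Raja miraletus	Mediterranean	Adriatic Sea	20	3	0.4684	0.1045	0.0009	0.0009	ref065
Raja montagui	Atlantic	Western Irish Sea	30	5	0.193	0.095	0.0003	0.0002	ref068
Raja polystigma	Mediterranean	Sicilian Strait	10	4	0.778	0.091	0.002	0.0003	ref068
Raja polystigma	Mediterranean	Tyrrhenian Sea	32	6	0.701	0.0815	0.0023	0.0003	ref068
Raja polystigma	Mediterranean	Sardinia	37	9	0.8255	0.0515	0.0025	0.0003	ref068
Raja polystigma	Mediterranean	Algerian Coasts	13	4	0.654	0.106	0.0019	0.0003	ref068
Raja radula	Mediterranean	Malta	22	3	0.437	0.105	0.0008	0.0008	ref063
Rajella fyllae	Atlantic	Northeast Atlantic	10	4	0.778	NA	0.0027	NA	ref060
Rajella fyllae	Atlantic	Canada	19	1	0	NA	0	NA	ref061
Rajella lintea	Atlantic	Northeast Atlantic	10	1	0	NA	0	NA	ref060
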