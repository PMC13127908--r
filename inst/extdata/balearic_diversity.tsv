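species	n	nh	nh_a	h	h_sd	pi	pi_sd
Dipturus oxyrinchus	29	1	NA	0	0	0	0
Leucoraja naevus	27	3	NA	0.2108	0.1005	0.0008	0.0008
Raja brachyura	31	6	4	0.6753	0.0681	0.0014	0.0012
Raja miraletus	29	3	2	0.1355	0.0845	0.0004	0.0005
Raja polystigma	37	1	NA	0	0	0	0
Raja radula	28	3	3	0.1402	0.0871	0.0005	0.0006
Raja clavata	31	2	1	0.125	0.077	0.0002	0.0004
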