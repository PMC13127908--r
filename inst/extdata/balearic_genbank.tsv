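species	n	accessions
Dipturus oxyrinchus	1	KY949111
Dipturus oxyrinchus	2	KU761956-KU761957
Dipturus oxyrinchus	26	PV524769-PV524794
Leucoraja naevus	5	KY949101-KY949105
Leucoraja naevus	22	PV524795-PV524816
Raja brachyura	5	KY949096-KY949100
Raja brachyura	26	PV524817-PV524842
Raja miraletus	3	KY949085-KY949087
Raja miraletus	26	PV524843-PV524868
Raja polystigma	14	KY949056-KY949057;KY949059-KY949070
Raja polystigma	23	PV524869-PV524891
Raja radula	5	KY949096-KY949100
Raja radula	23	PV524892-PV524914
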