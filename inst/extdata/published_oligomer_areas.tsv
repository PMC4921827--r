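model	n	area_nm2
8TMH	2	28.7
8TMH	3	41.9
8TMH	4	47.2
8TMH	5	65.2
8TMH	6	82.1
7TMH_CESA	2	30.4
7TMH_CESA	3	44.4
7TMH_CESA	4	49.4
7TMH_CESA	5	62.1
7TMH_CESA	6	88.0
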