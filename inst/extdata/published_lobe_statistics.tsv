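group	geometry	perimeter_mean	perimeter_sd	diameter_mean	diameter_sd	lobe_area_mean	lobe_area_sd	n_particles	n_lobes
original	circle	78.4	4.9	24.9	1.6	39.9	6.5	324	300
original	hexagon	74.8	4.5	21.4	1.3	NA	NA	324	NA
isac_sparx	circle	76.8	2.5	24.3	0.8	37.6	3.3	6	36
isac_sparx	hexagon	78.0	3.1	22.5	0.9	NA	NA	6	NA
relion	circle	78.2	0.4	24.9	0.1	42.0	2.7	2	12
relion	hexagon	79.9	1.5	23.1	0.4	NA	NA	2	NA
eman2	circle	76.4	2.3	24.3	0.7	36.7	4.9	6	36
eman2	hexagon	78.7	1.9	22.7	0.5	NA	NA	6	NA
lobe_classes_6	NA	NA	NA	NA	NA	40.6	4.4	NA	6
lobe_classes_12	NA	NA	NA	NA	NA	38.7	2.9	NA	12
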