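key	value	description
perimeter_circle	78.4	mean perimeter of original images, circular geometry (nm)
perimeter_hexagon	74.8	mean perimeter of original images, hexagonal geometry (nm)
diameter_circle	24.9	mean diameter of original images, circular geometry (nm)
diameter_hexagon	21.4	mean diameter of original images, hexagonal geometry (nm)
mean_diameter_original	23.1	mean diameter over both geometries, original images (nm)
mean_diameter_class_avg	23.6	mean diameter over clear class averages (nm)
mean_lobe_area_original	39.9	mean traced lobe area, original images (nm^2)
mean_lobe_area_class_avg	39.1	mean lobe area from class averages (nm^2)
overall_mean_lobe_area	39.5	overall mean lobe area (unweighted mean of group means, nm^2)
mean_tmh_diameter	23.4	overall mean diameter of the TMH region (nm)
opposite_lobe_spacing	17.0	mean centre-to-centre spacing of opposite lobes (nm)
trimer_area_8tmh	41.9	trimer cross-sectional area, 8 TMH model (nm^2)
trimer_area_7tmh	44.4	trimer TMH cross-sectional area, 7 TMH CESA model (nm^2)
cytosolic_diameter_model	32.8	cytosolic diameter of the six-fold trimer assembly (nm)
cytosolic_diameter_rounded	30	average predicted cytosolic diameter of the rosette CSC (nm)
saxs_sixfold_diameter	27	maximum diameter of the six-fold SAXS schematic (nm)
negstain_trimer_area	108.7	negative-stain class average area of the cytosolic trimer (nm^2)
computational_trimer_area	104.1	maximum cross-sectional area of the computational cytosolic trimer (nm^2)
saxs_trimer_area	99.6	maximum cross-sectional area of the SAXS cytosolic trimer (nm^2)
five_lobe_fraction	0.09	fraction of five-lobed or indistinct particles
n_picked	497	rosette CSC images picked
n_measured	324	six-lobed rosette CSCs measured
n_lobe_measurements	300	individual lobe perimeter measurements
n_lobes_picked	916	individual lobes picked for class averaging
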