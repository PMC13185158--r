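# Binding-site residues of the 426-aa reference RhlB, transcribed from the
# published docking heatmaps and motif searches. Product (M-RL) sites are
# context only and never trigger candidate exclusion. The GTP docking set is
# not printed residue-by-residue in the source and is omitted.
# AC score: total complex energy (force field + solvation); SwissParam
# score: weighted binding free energy.
pos	ligand	source	note	ac_score	swissparam_score
9	substrate_sugar	docking	hydrogen bond, short loop p7-13	-314.62	-9.81
10	substrate_sugar	docking	hydrogen bond	-314.62	-9.81
13	substrate_sugar	docking	hydrogen + ionic bond	-314.62	-9.81
231	substrate_sugar	docking	hydrophobic bond, long loop	-314.62	-9.81
259	substrate_sugar	docking	1 hydrogen bond, medium loop	-314.62	-9.81
260	substrate_sugar	docking	3 hydrogen bonds, medium loop	-314.62	-9.81
306	substrate_sugar	docking	hydrophobic bond, alpha-turn	-314.62	-9.81
309	substrate_sugar	docking	hydrophobic bond, alpha12	-314.62	-9.81
324	substrate_sugar	docking	hydrogen bond, beta-turn	-314.62	-9.81
325	substrate_sugar	docking	hydrogen bond, alpha13	-314.62	-9.81
346	substrate_sugar	docking	hydrogen bond, short loop	-314.62	-9.81
347	substrate_sugar	docking	hydrogen bond, alpha14	-314.62	-9.81
228	substrate_lipid	docking	multiple hydrogen bonds, long loop	-66.36	-6.8
229	substrate_lipid	docking	multiple hydrogen bonds, long loop	-66.36	-6.8
231	substrate_lipid	docking	multiple hydrogen bonds, long loop	-66.36	-6.8
233	substrate_lipid	docking	multiple hydrogen bonds, long loop	-66.36	-6.8
330	substrate_lipid	docking	1 hydrogen bond, alpha13	-66.36	-6.8
22	product	docking	ionic bond, simulation 1	-32.05	-7.4
230	product	docking	hydrophobic bond, simulation 1	-32.05	-7.4
333	product	docking	hydrophobic bond, simulation 1	-32.05	-7.4
396	product	docking	2 hydrogen bonds, simulation 1	-32.05	-7.4
11	product	docking	simulation 2	-30.6	-9.034
15	product	docking	simulation 2	-30.6	-9.034
260	product	docking	simulation 2	-30.6	-9.034
286	product	docking	simulation 2	-30.6	-9.034
306	product	docking	simulation 2	-30.6	-9.034
309	product	docking	simulation 2	-30.6	-9.034
326	product	docking	simulation 2	-30.6	-9.034
10	atp	docking	shared with dTDP-L-rhamnose	NA	NA
13	atp	docking	shared with dTDP-L-rhamnose	NA	NA
260	atp	docking	shared with dTDP-L-rhamnose	NA	NA
263	atp	docking	putative ATP site, beta8-alpha11 loop	NA	NA
306	atp	docking	shared with dTDP-L-rhamnose	NA	NA
346	atp	docking	shared with dTDP-L-rhamnose	NA	NA
347	atp	docking	shared with dTDP-L-rhamnose	NA	NA
305	atp	motif	alpha-turn AYAP p305-308	NA	NA
306	atp	motif	alpha-turn AYAP p305-308	NA	NA
307	atp	motif	alpha-turn AYAP p305-308	NA	NA
308	atp	motif	alpha-turn AYAP p305-308	NA	NA
321	gtp	motif	beta-turn PGG p321-324	NA	NA
322	gtp	motif	beta-turn PGG p321-324	NA	NA
323	gtp	motif	beta-turn PGG p321-324	NA	NA
324	gtp	motif	beta-turn PGG p321-324	NA	NA
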