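# Structural annotation of the 426-aa reference RhlB, transcribed from the
# published structure/docking figures. Active-domain boundaries are shown
# only graphically in the source: the A/B intervals below are approximate
# and user-editable. Secondary-structure rows list only intervals whose
# residue bounds are quoted explicitly.
category	label	start	end	length_class	note
domain	A	1	200	NA	approximate, user-editable
domain	B	201	426	NA	approximate, user-editable
helix	alpha5	74	95	NA	contains S94
helix	alpha7	110	199	NA	transmembrane anchoring domain
helix	alpha12	309	315	NA	adjoins alpha-turn p305-308
helix	alpha13	325	333	NA	13th helix, p330 HAAs contact
helix	alpha14	347	357	NA	adjoins short loop p341-346
sheet	beta30_35	30	35	NA	hydrophobic partner of p21
turn	alpha_turn_AYAP	305	308	short	putative ATP site
turn	beta_turn_PGG	322	324	short	GTP site quoted as p321-324 and p322-324; 322-324 used
loop	short_loop_N	7	13	short	dTDP contacts p9/p10/p13
loop	long_loop	225	240	long	HAAs binding loop
loop	medium_loop	258	266	medium	dTDP contacts p259/p260
loop	short_loop_C	341	346	short	dTDP contact p346
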