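pathway	category	clause_index	alternatives	negated
nitrogen_fixation	nitrogen	1	nifH	FALSE
nitrogen_fixation	nitrogen	2	nifD	FALSE
nitrogen_fixation	nitrogen	3	nifK	FALSE
denitrification	nitrogen	1	narG|napA	FALSE
denitrification	nitrogen	2	nirK|nirS	FALSE
denitrification	nitrogen	3	norB	FALSE
denitrification	nitrogen	4	nosZ	FALSE
dnra	nitrogen	1	nrfA	FALSE
nitrification_partial	nitrogen	1	hao	FALSE
nitrification_partial	nitrogen	2	amoA|amoB	TRUE
anammox	nitrogen	1	hzo	FALSE
sulfate_reduction	sulfur	1	sat	FALSE
sulfate_reduction	sulfur	2	aprA|aprB	FALSE
sulfate_reduction	sulfur	3	dsrA|dsrB	FALSE
sulfur_oxidation	sulfur	1	soxA|soxX	FALSE
sulfur_oxidation	sulfur	2	soxB	FALSE
sulfur_oxidation	sulfur	3	soxY|soxZ	FALSE
wood_ljungdahl	carbon_fixation	1	cooS|acsA	FALSE
wood_ljungdahl	carbon_fixation	2	acsB	FALSE
wood_ljungdahl	carbon_fixation	3	fhs	FALSE
calvin	carbon_fixation	1	rbcL|rbcL_II_III|rbcL_III_like	FALSE
methanogenesis_h2	methane	1	mcrA	FALSE
methanogenesis_h2	methane	2	mcrB|mcrG	FALSE
methanogenesis_h2	methane	3	NiFe_G1|NiFe_G3|frhA	FALSE
methanogenesis_h2	methane	4	ackA|pta|mtaB|mttB	TRUE
rnf_complex	energy	1	rnfC	FALSE
rnf_complex	energy	2	rnfA|rnfB|rnfD|rnfE|rnfG	FALSE
formate_dehydrogenase	energy	1	fdhA|fdoG	FALSE
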