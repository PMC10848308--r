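centre	label	biomolecule	window_policy	half_width
3011	unsat_fa	unsaturated fatty acids (cis C=CH stretch)	zero_crossing	12
2960	methyl_lipid_protein	methyl groups of lipids and proteins	zero_crossing	12
2921	sat_lipid_2921	saturated lipids (CH2 asym. stretch)	zero_crossing	12
2852	sat_lipid_2852	saturated lipids (CH2 sym. stretch)	zero_crossing	12
1744	lipid_ester	lipid ester carbonyl / fatty acids	zero_crossing	12
1549	protein_amide2	protein amide II	zero_crossing	12
1400	carboxylate	carboxylated molecules (COO- sym. stretch)	zero_crossing	12
1377	lipid_ch2	lipids/proteins CH bend (CH-stretch II family)	zero_crossing	12
1241	phosphoryl	phosphorylated molecules (PO2- asym. stretch)	zero_crossing	12
1146	carbohydrate	carbohydrates (C-O stretch)	zero_crossing	12
1080	silica	silica (Si-O stretch)	zero_crossing	12
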