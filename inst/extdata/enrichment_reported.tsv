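setting	gene_set	category	direction	fdr	p_value
cisplatin_acute	Adherens junction	Cellular Processes; Cell Communication	down	0.07	0.003
cisplatin_acute	Focal adhesion	Cellular Processes; Cell Communication	down	0.04	<0.0001
bleomycin_acute	p53 signalling pathway	Cellular Processes; Cell Growth and Death	up	0.001	<0.0001
cisplatin_acute	p53 signalling pathway	Cellular Processes; Cell Growth and Death	up	0.02	<0.0001
cisplatin_chronic	p53 signalling pathway	Cellular Processes; Cell Growth and Death	down	0.1	<0.0001
cisplatin_acute	TGF-beta signalling pathway	Environmental Information Processing; Signal Transduction	down	0.05	<0.0001
cisplatin_acute	Ubiquitin mediated proteolysis	Genetic Information Processing; Folding, Sorting and Degradation	down	0.04	0.001
cisplatin_acute	Endometrial cancer	Human Diseases	down	0.04	<0.0001
bleomycin_acute	Cholera infection	Human Diseases	up	0.10	0.005
bleomycin_acute	Type I Diabetes Mellitus	Human Diseases	up	0.07	<0.0001
cisplatin_acute	Type I Diabetes Mellitus	Human Diseases	up	0.05	<0.0001
cisplatin_chronic	Type I Diabetes Mellitus	Human Diseases	down	0.01	<0.0001
cisplatin_chronic	Neurodegerative disease	Human Diseases	down	0.09	0.008
cisplatin_chronic	Prion diseases	Human Diseases	down	0.08	0.01
bleomycin_acute	Butanoate metabolism	Metabolism; Carbohydrate Metabolism	up	0.02	<0.0001
cisplatin_acute	Glyoxylate and dicarboxylate metabolism	Metabolism; Carbohydrate Metabolism	down	0.09	0.02
cisplatin_acute	Reductive carboxylate cycle	Metabolism; Carbohydrate Metabolism	down	0.04	0.002
bleomycin_acute	Glycosylphosphatidylinositol(GPI)-anchor biosynthesis	Metabolism; Carbohydrate Metabolism	up	0.03	0.002
cisplatin_acute	N-Glycan biosynthesis	Metabolism; Carbohydrate Metabolism	down	0.08	<0.0001
bleomycin_acute	Linoleic acid metabolism	Metabolism; Carbohydrate Metabolism	up	0.08	0.005
cisplatin_acute	Linoleic acid metabolism	Metabolism; Carbohydrate Metabolism	up	0.09	0.01
cisplatin_acute	Polyunsatyrated fatty acid biosynthesis	Metabolism; Carbohydrate Metabolism	down	0.04	0.002
cisplatin_chronic	Antigen processing and presentation	Organismal Systems; Immune System	down	0.0	<0.0001
cisplatin_chronic	Toll-like receptor signalling pathway	Organismal Systems; Immune System	down	0.08	<0.0001
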