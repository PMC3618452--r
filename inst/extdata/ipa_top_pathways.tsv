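# Published IPA over-representation output for the MK-801 rat study:
# top canonical pathways per brain region (and the metabolite+protein
# integrated analysis), with the printed Fisher p-value, hit count,
# pathway size and coverage ratio. The cortex "Glycine, Serine and
# Threonine Metabolism" row is internally inconsistent as printed
# (3/150 = 0.020, printed ratio 0.027); flagged in `consistent`.
analysis	pathway	p_printed	hits	size	ratio_printed	consistent
cortex	Alanine and Aspartate Metabolism	1.60e-06	5	88	0.057	TRUE
cortex	Glutamate Metabolism	9.05e-05	4	78	0.051	TRUE
cortex	Taurine and Hypotaurine Metabolism	1.85e-04	3	47	0.064	TRUE
cortex	Aminoacyl-tRNA Biosynthesis	4.59e-04	4	84	0.048	TRUE
cortex	Citrate Cycle	8.21e-04	3	58	0.052	TRUE
cortex	GABA Receptor Signaling	8.29e-04	2	56	0.036	TRUE
cortex	Nitrogen Metabolism	1.56e-03	3	133	0.023	TRUE
cortex	Glycine, Serine and Threonine Metabolism	6.74e-03	3	150	0.027	FALSE
cortex	Sulfur Metabolism	8.25e-03	2	61	0.033	TRUE
cortex	Selenoamino Acid Metabolism	1.06e-02	2	77	0.026	TRUE
hippocampus	GABA Receptor Signaling	6.75e-06	3	56	0.054	TRUE
hippocampus	Aminoacyl-tRNA Biosynthesis	2.36e-05	5	84	0.06	TRUE
hippocampus	Glycine, Serine and Threonine Metabolism	2.65e-05	5	150	0.033	TRUE
hippocampus	Glutamate Metabolism	9.05e-05	4	78	0.051	TRUE
hippocampus	Cyanoamino Acid Metabolism	5.12e-04	3	64	0.047	TRUE
hippocampus	Arginine and Proline Metabolism	1.13e-03	4	183	0.022	TRUE
hippocampus	D-glutamine and D-glutamate Metabolism	1.24e-03	2	27	0.074	TRUE
hippocampus	Butanoate Metabolism	1.39e-03	3	132	0.023	TRUE
hippocampus	Alanine and Aspartate Metabolism	1.39e-03	3	88	0.034	TRUE
hippocampus	Nitrogen Metabolism	1.56e-03	3	133	0.023	TRUE
integrated	Citrate Cycle	3.47e-14	9	57	0.158	TRUE
integrated	Alanine and Aspartate Metabolism	1.12e-09	7	82	0.085	TRUE
integrated	Oxidative Phosphorylation	3.03e-08	8	159	0.05	TRUE
integrated	Glutamate Metabolism	4.35e-08	6	75	0.08	TRUE
integrated	Mitochondrial Dysfunction	5.6e-07	7	175	0.04	TRUE
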