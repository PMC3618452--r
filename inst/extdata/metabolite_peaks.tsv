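metabolite	kegg_id	center_ppm	relative_intensity	halfwidth_ppm
Lactate	C00186	1.325	3	0.005
Lactate	C00186	4.110	1	0.005
NAA	C01042	2.010	3	0.005
NAA	C01042	2.490	1	0.005
NAA	C01042	2.675	1	0.005
NAA	C01042	4.380	1	0.005
Creatine	C00300	3.030	3	0.005
Creatine	C00300	3.925	2	0.005
Acetate	C00033	1.920	3	0.005
GABA	C00334	1.890	2	0.005
GABA	C00334	2.280	2	0.005
GABA	C00334	3.010	2	0.005
Phosphorylcholine	C00588	3.215	9	0.005
Phosphorylcholine	C00588	3.580	2	0.005
Phosphorylcholine	C00588	4.160	2	0.005
Choline	C00114	3.185	9	0.005
Choline	C00114	3.500	2	0.005
L-Valine	C00183	0.990	3	0.005
L-Valine	C00183	1.040	3	0.005
L-Valine	C00183	2.258	1	0.005
L-Alanine	C00041	1.470	3	0.005
L-Glutamate	C00025	2.080	2	0.005
L-Glutamate	C00025	2.340	2	0.005
L-Glutamate	C00025	3.745	1	0.005
L-Glutamine	C00064	2.135	2	0.005
L-Glutamine	C00064	2.440	2	0.005
L-Glutamine	C00064	3.770	1	0.005
L-Aspartate	C00049	2.705	1	0.005
L-Aspartate	C00049	2.820	1	0.005
L-Aspartate	C00049	3.890	1	0.005
Myo-inositol	C00137	3.270	2	0.005
Myo-inositol	C00137	3.610	2	0.005
Myo-inositol	C00137	4.055	1	0.005
Taurine	C00245	3.250	2	0.005
Taurine	C00245	3.420	2	0.005
Succinate	C00042	2.400	4	0.005
Citrate	C00158	2.535	2	0.005
Citrate	C00158	2.625	2	0.005
Scyllo-inositol	C06153	3.345	6	0.005
L-Serine	C00065	3.835	1	0.005
L-Serine	C00065	3.955	2	0.005
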