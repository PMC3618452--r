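metabolite	kegg_id	lo_ppm	hi_ppm
Lactate	C00186	1.310	1.340
Lactate	C00186	4.095	4.125
NAA	C01042	1.995	2.025
NAA	C01042	2.475	2.505
NAA	C01042	2.660	2.685
NAA	C01042	4.365	4.395
Creatine	C00300	3.015	3.050
Creatine	C00300	3.910	3.940
Acetate	C00033	1.895	1.935
GABA	C00334	1.875	1.905
GABA	C00334	2.265	2.295
GABA	C00334	2.995	3.015
Phosphorylcholine	C00588	3.200	3.230
Phosphorylcholine	C00588	3.565	3.595
Phosphorylcholine	C00588	4.145	4.175
Choline	C00114	3.170	3.200
Choline	C00114	3.485	3.515
L-Valine	C00183	0.975	1.005
L-Valine	C00183	1.025	1.055
L-Valine	C00183	2.245	2.265
L-Alanine	C00041	1.455	1.485
L-Glutamate	C00025	2.060	2.100
L-Glutamate	C00025	2.325	2.355
L-Glutamate	C00025	3.730	3.760
L-Glutamine	C00064	2.115	2.150
L-Glutamine	C00064	2.425	2.455
L-Glutamine	C00064	3.760	3.790
L-Aspartate	C00049	2.690	2.720
L-Aspartate	C00049	2.805	2.835
L-Aspartate	C00049	3.875	3.905
Myo-inositol	C00137	3.265	3.290
Myo-inositol	C00137	3.595	3.625
Myo-inositol	C00137	4.040	4.070
Taurine	C00245	3.235	3.265
Taurine	C00245	3.405	3.435
Succinate	C00042	2.385	2.415
Citrate	C00158	2.520	2.550
Citrate	C00158	2.610	2.640
Scyllo-inositol	C06153	3.330	3.360
L-Serine	C00065	3.820	3.850
L-Serine	C00065	3.940	3.970
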