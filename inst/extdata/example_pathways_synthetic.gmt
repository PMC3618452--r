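Glutamate Metabolism	synthetic pathway set (KEGG compound IDs)	C00025	C00064	C00334	C00026	C00014	C00049	C00158
Citrate Cycle	synthetic pathway set (KEGG compound IDs)	C00158	C00042	C00122	C00149	C00036	C00026	C00091	C05379
GABA Receptor Signaling	synthetic pathway set (KEGG compound IDs)	C00334	C00025	C00064	C00026
Alanine and Aspartate Metabolism	synthetic pathway set (KEGG compound IDs)	C00041	C00049	C00025	C00026	C00036	C01042	C00022
Taurine and Hypotaurine Metabolism	synthetic pathway set (KEGG compound IDs)	C00245	C00519	C00065	C00022
Glycine, Serine and Threonine Metabolism	synthetic pathway set (KEGG compound IDs)	C00065	C00037	C00188	C00143	C00022	C00300
Glycolysis and Gluconeogenesis	synthetic pathway set (KEGG compound IDs)	C00022	C00186	C00031	C00036	C00074
Inositol Phosphate Metabolism	synthetic pathway set (KEGG compound IDs)	C00137	C06153	C01177	C00031
Membrane Lipid Precursors	synthetic pathway set (KEGG compound IDs)	C00114	C00588	C00570	C00307
Branched Chain Amino Acid Degradation	synthetic pathway set (KEGG compound IDs)	C00183	C00123	C00407	C00141
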