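C00014
C00022
C00025
C00026
C00031
C00033
C00036
C00037
C00041
C00042
C00049
C00064
C00065
C00074
C00091
C00114
C00122
C00123
C00137
C00141
C00143
C00149
C00158
C00183
C00186
C00188
C00245
C00300
C00307
C00334
C00407
C00519
C00570
C00588
C01042
C01177
C05379
C06153
C00047
C00062
C00073
C00078
C00079
C00082
C00097
C00135
C00148
C00152
C00163
C00164
C00207
C00212
C00246
C00249
C00255
C00262
C00270
C00327
C00319
C00346
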