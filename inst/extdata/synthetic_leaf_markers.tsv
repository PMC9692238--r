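population	gene_id	weight
mesophyll_1	gene00903	1.134
mesophyll_1	gene00337	1.78
mesophyll_1	gene01396	1.375
mesophyll_1	gene00830	1.006
mesophyll_1	gene01751	1.453
mesophyll_1	gene00590	1.899
mesophyll_1	gene00379	1.541
mesophyll_1	gene01033	1.805
mesophyll_1	gene00536	0.463
mesophyll_1	gene01382	1.333
mesophyll_1	gene01190	1.756
mesophyll_1	gene01773	1.225
mesophyll_2	gene00789	1.979
mesophyll_2	gene01499	0.856
mesophyll_2	gene01193	0.593
mesophyll_2	gene00457	0.726
mesophyll_2	gene01774	1.724
mesophyll_2	gene01401	1.523
mesophyll_2	gene01125	0.769
mesophyll_2	gene00580	1.281
mesophyll_2	gene00290	1.221
mesophyll_2	gene00717	1.09
mesophyll_2	gene01198	1.545
mesophyll_2	gene01437	1.536
mesophyll_3	gene00027	1.075
mesophyll_3	gene00110	1.255
mesophyll_3	gene00028	1.146
mesophyll_3	gene00572	0.311
mesophyll_3	gene01845	0.954
mesophyll_3	gene00369	2.159
mesophyll_3	gene00228	1.221
mesophyll_3	gene01020	0.872
mesophyll_3	gene01947	1.337
mesophyll_3	gene01418	2.088
mesophyll_3	gene01260	0.806
mesophyll_3	gene00828	1.675
mesophyll_4	gene01067	0.764
mesophyll_4	gene01061	1.306
mesophyll_4	gene00423	2.539
mesophyll_4	gene01765	1.099
mesophyll_4	gene00879	1.243
mesophyll_4	gene01126	1.94
mesophyll_4	gene01597	0.661
mesophyll_4	gene01459	1.995
mesophyll_4	gene01336	1.576
mesophyll_4	gene00337	2.476
mesophyll_4	gene00606	0.245
mesophyll_4	gene00299	1.031
mesophyll_5	gene00637	1.396
mesophyll_5	gene01692	1.534
mesophyll_5	gene00668	0.484
mesophyll_5	gene00096	1.488
mesophyll_5	gene00241	0.205
mesophyll_5	gene00741	2.172
mesophyll_5	gene00873	0.853
mesophyll_5	gene00941	1.204
mesophyll_5	gene01793	1.36
mesophyll_5	gene01873	1.777
mesophyll_5	gene00933	1.923
mesophyll_5	gene01921	0.413
bundle_sheath_1	gene01530	0.995
bundle_sheath_1	gene00770	1.588
bundle_sheath_1	gene01899	1.433
bundle_sheath_1	gene00559	1.829
bundle_sheath_1	gene01609	1.489
bundle_sheath_1	gene01372	1.688
bundle_sheath_1	gene01233	2.173
bundle_sheath_1	gene00419	2.023
bundle_sheath_1	gene01286	0.408
bundle_sheath_1	gene00274	1.372
bundle_sheath_1	gene01076	0.753
bundle_sheath_1	gene01130	0.071
bundle_sheath_2	gene01121	1.509
bundle_sheath_2	gene00439	1.325
bundle_sheath_2	gene00078	1.76
bundle_sheath_2	gene00260	1.257
bundle_sheath_2	gene00606	1.378
bundle_sheath_2	gene00724	0.82
bundle_sheath_2	gene00642	0.178
bundle_sheath_2	gene00690	0.968
bundle_sheath_2	gene01204	1.328
bundle_sheath_2	gene01247	1.54
bundle_sheath_2	gene00270	1.115
bundle_sheath_2	gene01755	1.74
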