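"lag_s","G"
5e-05,0.510695488658173
1e-04,0.504679622370176
0.00015,0.496358707583848
2e-04,0.488396865148528
0.00025,0.481949103092273
3e-04,0.472994672454784
0.00035,0.462989295104349
4e-04,0.460266973644401
0.00045,0.450671308676153
5e-04,0.441733049852747
0.00055,0.434371524986065
6e-04,0.429963892034121
0.00065,0.423055629074024
7e-04,0.418224159299728
0.00075,0.410662389408382
8e-04,0.406566137800733
9e-04,0.394690161202713
0.001,0.382819372872257
0.0011,0.369962822237304
0.0012,0.362177328406873
0.0013,0.349645619969012
0.0014,0.342658736278059
0.0015,0.333625711253965
0.0016,0.326299272867647
0.0018,0.309209327226211
0.002,0.292918201254966
0.0022,0.280069807780333
0.0024,0.268280947039324
0.0026,0.258511725001553
0.0028,0.24891892904287
0.003,0.237008196204433
0.0032,0.22561118213714
0.0036,0.208377338521966
0.004,0.192585421100423
0.0044,0.180635854579565
0.0048,0.166549300234816
0.0052,0.156717871758834
0.0056,0.147976028232932
0.006,0.142344918514629
0.0064,0.136812729915029
0.0072,0.125495352686525
0.008,0.110795162788904
0.0088,0.0983350264127738
0.0096,0.0890334180659595
0.0104,0.0782325561404005
0.0112,0.0693246033490484
0.012,0.0668275543138519
0.0128,0.0650438521175813
0.0144,0.0577991034073331
0.016,0.0521356661577606
0.0176,0.0485466007114943
0.0192,0.046043563571617
0.0208,0.0484808201753182
0.0224,0.0484943379585023
0.024,0.0424135984193805
0.0256,0.0290548227417362
0.0288,0.00724060029252716
0.032,0.0041447261740255
0.0352,-0.0040764245328101
0.0384,-0.00882871996806167
0.0416,0.00404659694895093
0.0448,0.0213282640403341
0.048,0.0141115207551754
0.0512,0.00831524623215829
0.0576,0.0032268518854639
0.064,0.0131620159928485
0.0704,0.0370263783199991
0.0768,0.0338546509047335
0.0832,0.0376786944628531
0.0896,0.0343747530616292
0.096,0.0348888858097931
0.1024,0.00106477096445734
0.1152,-0.0139485357453415
0.128,-0.0219876042547361
0.1408,-0.0240674321111488
0.1536,-0.0435365308936254
0.1664,-0.0350808561419718
0.1792,-0.0544511079588832
0.192,-0.0489772260453584
0.2048,-0.0378584473941327
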