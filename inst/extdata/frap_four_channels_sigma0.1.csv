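"time_s","intensity_norm"
0.0769315068493151,0.111567372283837
1.62542465753425,0.168089997860869
3.17391780821918,0.213196551903756
4.72241095890411,0.258767915454943
6.27090410958904,0.296544798891665
7.81939726027397,0.334167132343444
9.36789041095891,0.372547961311714
10.9163835616438,0.402405485648034
12.4648767123288,0.430148363464277
14.0133698630137,0.455304976311391
15.5618630136986,0.491077735809882
17.1103561643836,0.511172836640024
18.6588493150685,0.523646249366859
20.2073424657534,0.561135510896956
21.7558356164384,0.562762557098803
23.3043287671233,0.5961578084367
24.8518356164384,0.615284990393235
26.4003287671233,0.641050865417848
27.9488219178082,0.663911100624315
29.4973150684932,0.664525628450113
31.0458082191781,0.685596738289888
32.594301369863,0.703404199966956
34.142794520548,0.704806136045595
35.6912876712329,0.727532385070849
37.2397808219178,0.733727089112724
38.7882739726027,0.736422794847511
40.3367671232877,0.751436742493114
41.8852602739726,0.754810682844431
43.4337534246575,0.768362347737146
44.9822465753425,0.769090903113735
46.5307397260274,0.778188775860074
48.0792328767123,0.807778994490927
49.6277260273973,0.806478197205092
51.1762191780822,0.802665439351971
52.7247123287671,0.809629973726429
54.2732054794521,0.823734542752675
55.821698630137,0.825753436831245
57.3701917808219,0.844500091524932
58.9186849315069,0.83442475825179
60.4671780821918,0.844090062847157
62.0146849315069,0.844081263371346
63.5631780821918,0.850093993704915
65.1116712328767,0.858730797623014
66.6601643835616,0.850714163681169
68.2086575342466,0.868449238491381
69.7571506849315,0.869678777814263
71.3056438356165,0.866309613110439
72.8541369863014,0.866955465368807
74.4026301369863,0.872731444541694
75.9511232876713,0.874359039438668
77.4996164383562,0.886480871399158
79.0481095890411,0.868093037651697
80.596602739726,0.882450120715519
82.145095890411,0.87339283189802
83.6935890410959,0.893170030075547
85.2420821917808,0.885696251718934
86.7905753424658,0.890725875789716
88.3390684931507,0.891756118298453
89.8875616438356,0.885890206723322
91.4360547945206,0.887638964520874
92.9845479452055,0.905604056185481
94.5330410958904,0.90115428894111
96.0815342465754,0.893930425116421
97.6300273972603,0.911706825256602
99.1785205479452,0.9043634237214
100.72602739726,0.898636799669909
102.274520547945,0.898561968480832
103.82301369863,0.909778532118445
105.371506849315,0.90005582960653
106.92,0.890206232341371
108.468493150685,0.911695013678695
110.01698630137,0.901830741833203
111.565479452055,0.905575671071744
113.11397260274,0.900305819878809
114.662465753425,0.905673970793722
116.21095890411,0.908449451777133
117.759452054795,0.918966267980035
119.307945205479,0.921818878022191
120.856438356164,0.901513141421625
122.404931506849,0.938837292560805
123.953424657534,0.915964710918158
125.501917808219,0.905091103297673
127.050410958904,0.908708703434121
128.598904109589,0.913669835490293
130.147397260274,0.908600469919646
131.695890410959,0.91489861774377
133.244383561644,0.916258985717642
134.792876712329,0.927603061888159
136.341369863014,0.903726611208005
137.888876712329,0.917757858824829
139.437369863014,0.907683272292214
140.985863013699,0.904925850512679
142.534356164384,0.924243001459571
144.082849315069,0.909094156928079
145.631342465753,0.90933250693885
147.179835616438,0.896751649026372
148.728328767123,0.93087468375644
150.276821917808,0.910847173690159
151.825315068493,0.920838682611161
153.373808219178,0.890725328829214
154.922301369863,0.91550993826912
156.470794520548,0.917150145149151
158.019287671233,0.905010651359512
159.567780821918,0.910090669338765
161.116273972603,0.921927981840005
162.664767123288,0.906939871799989
164.213260273973,0.914432197124301
165.761753424658,0.924001576891712
167.310246575342,0.92521363789154
168.858739726027,0.936220465087907
170.407232876712,0.929373616971202
171.955726027397,0.915605144466929
173.504219178082,0.919081606035746
175.052712328767,0.926073546875536
176.600219178082,0.919545214309289
178.148712328767,0.914888369858854
179.697205479452,0.917279894635543
181.245698630137,0.91611207021145
182.794191780822,0.905689815860628
184.342684931507,0.928144835256109
185.891178082192,0.928068076393465
187.439671232877,0.926502558171359
188.988164383562,0.9215806407966
190.536657534247,0.906964197922455
192.085150684932,0.90742700112989
193.633643835616,0.912732290075226
195.182136986301,0.915476947920885
196.730630136986,0.921615996901232
198.279123287671,0.934166783551029
199.827616438356,0.916618883936552
201.376109589041,0.921044202589392
202.924602739726,0.919570165559416
204.473095890411,0.922559529968281
206.021589041096,0.909274622736805
207.570082191781,0.914588923730356
209.118575342466,0.9071486603632
210.667068493151,0.921720255581281
212.215561643836,0.917467944203948
213.763068493151,0.923097405576904
215.311561643836,0.916399176381652
216.860054794521,0.915355306682276
218.408547945206,0.922348353940256
219.95704109589,0.9311738072449
221.505534246575,0.9106598086607
223.05402739726,0.921584362374843
224.602520547945,0.918907818102579
226.15101369863,0.91194213883338
227.699506849315,0.912855033434439
229.248,0.923455724935356
230.796493150685,0.925089738170902
232.34498630137,0.925946391342647
233.893479452055,0.91947112791139
235.44197260274,0.916242009013645
236.990465753425,0.916138180798324
238.53895890411,0.912445344083315
240.087452054795,0.913974293894401
241.635945205479,0.918996110961554
243.184438356164,0.91820260156465
244.732931506849,0.926453651334576
246.281424657534,0.924511186086744
247.829917808219,0.915888312975544
249.378410958904,0.915924198480248
250.926904109589,0.914435039134621
252.474410958904,0.894796911171432
254.022904109589,0.926619926260327
255.571397260274,0.911857630943945
257.119890410959,0.922017537564571
258.668383561644,0.921327600770452
260.216876712329,0.916412499851496
261.765369863014,0.913321040577324
263.313863013699,0.919358135719746
264.862356164384,0.903375838971368
266.410849315069,0.907897508232307
267.959342465753,0.933227992541566
269.507835616438,0.910656592563854
271.056328767123,0.911217266914458
272.604821917808,0.921134828410925
274.153315068493,0.914733071545698
275.701808219178,0.915820638041707
277.250301369863,0.914853888977135
278.798794520548,0.935059745593782
280.347287671233,0.911711906469724
281.895780821918,0.914745762173485
283.444273972603,0.929479427276328
284.992767123288,0.917928756399819
286.541260273973,0.921913403648579
288.089753424658,0.917017214455207
289.637260273973,0.915412154363597
291.185753424658,0.925581534439431
292.734246575343,0.931951907348785
294.282739726027,0.936121424176157
295.831232876712,0.914933327645429
297.379726027397,0.934270397676931
298.928219178082,0.918137483416685
300.476712328767,0.896055187758987
302.025205479452,0.918409359794938
303.573698630137,0.925961665886401
305.122191780822,0.906513205869399
306.670684931507,0.914173279838874
308.219178082192,0.913697429563079
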