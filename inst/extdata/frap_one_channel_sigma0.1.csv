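"time_s","intensity_norm"
0.0769315068493151,0.107870088337057
1.62542465753425,0.14709702757961
3.17391780821918,0.174814959378337
4.72241095890411,0.195419021486012
6.27090410958904,0.217735253529468
7.81939726027397,0.23779374970886
9.36789041095891,0.262646492336843
10.9163835616438,0.270673092787688
12.4648767123288,0.296059699193993
14.0133698630137,0.31509723397572
15.5618630136986,0.333828114584004
17.1103561643836,0.343076870914813
18.6588493150685,0.36214353396523
20.2073424657534,0.373364492580673
21.7558356164384,0.391402736894605
23.3043287671233,0.4029482241646
24.8518356164384,0.420466839589897
26.4003287671233,0.428691297457104
27.9488219178082,0.445976477389888
29.4973150684932,0.450138528165916
31.0458082191781,0.45934807249444
32.594301369863,0.474238412574839
34.142794520548,0.497658908392222
35.6912876712329,0.495883940611814
37.2397808219178,0.522048409323781
38.7882739726027,0.521356867704456
40.3367671232877,0.536391100179188
41.8852602739726,0.53561021037693
43.4337534246575,0.554700293741781
44.9822465753425,0.56141283204212
46.5307397260274,0.566927319165374
48.0792328767123,0.580531607523345
49.6277260273973,0.594161060221309
51.1762191780822,0.602776990157945
52.7247123287671,0.594834988481142
54.2732054794521,0.613678414314525
55.821698630137,0.625368314356823
57.3701917808219,0.625947346306083
58.9186849315069,0.635970166206986
60.4671780821918,0.643362766015088
62.0146849315069,0.639025798404837
63.5631780821918,0.655798973741741
65.1116712328767,0.65823543732357
66.6601643835616,0.660615032825291
68.2086575342466,0.669303283445058
69.7571506849315,0.666512987726356
71.3056438356165,0.687545759732114
72.8541369863014,0.67078912692378
74.4026301369863,0.693075542592959
75.9511232876713,0.696828646950846
77.4996164383562,0.709218894389463
79.0481095890411,0.711770620309073
80.596602739726,0.712286501276049
82.145095890411,0.720037673975078
83.6935890410959,0.732063923135359
85.2420821917808,0.732002796051943
86.7905753424658,0.731230689395954
88.3390684931507,0.736245437103326
89.8875616438356,0.75112927740885
91.4360547945206,0.737785367300386
92.9845479452055,0.759919720663969
94.5330410958904,0.746014674572386
96.0815342465754,0.760997085367553
97.6300273972603,0.75522727984521
99.1785205479452,0.753030609268057
100.72602739726,0.753933685589406
102.274520547945,0.761668062862325
103.82301369863,0.774378633022848
105.371506849315,0.780717561499765
106.92,0.785930589773749
108.468493150685,0.781218874041267
110.01698630137,0.795730546477177
111.565479452055,0.79028564432357
113.11397260274,0.795089555472154
114.662465753425,0.790682177309615
116.21095890411,0.804728088759323
117.759452054795,0.802298820260435
119.307945205479,0.800439785023614
120.856438356164,0.816472781593834
122.404931506849,0.802484826770689
123.953424657534,0.81762501597762
125.501917808219,0.81015696491145
127.050410958904,0.810910832467883
128.598904109589,0.817214864600483
130.147397260274,0.816893019748777
131.695890410959,0.834061442668197
133.244383561644,0.826723857686372
134.792876712329,0.829978006335391
136.341369863014,0.828438282942542
137.888876712329,0.834817182625923
139.437369863014,0.84140252883181
140.985863013699,0.837846010218566
142.534356164384,0.836733166064204
144.082849315069,0.840829011845894
145.631342465753,0.832052500671997
147.179835616438,0.838126731899632
148.728328767123,0.849715253000093
150.276821917808,0.84136401870545
151.825315068493,0.843375316810002
153.373808219178,0.8421098837778
154.922301369863,0.838369625436724
156.470794520548,0.859455496633739
158.019287671233,0.852445198691586
159.567780821918,0.852215319401994
161.116273972603,0.854952945709185
162.664767123288,0.831958343210353
164.213260273973,0.847785376142911
165.761753424658,0.860234795508088
167.310246575342,0.859977921164514
168.858739726027,0.854096956538292
170.407232876712,0.873650703125276
171.955726027397,0.87716715763333
173.504219178082,0.859298665945025
175.052712328767,0.869682992570878
176.600219178082,0.867368365668844
178.148712328767,0.867636449440442
179.697205479452,0.866997275632987
181.245698630137,0.869702346841949
182.794191780822,0.872621883801309
184.342684931507,0.884142470349333
185.891178082192,0.883537994163522
187.439671232877,0.877692812409683
188.988164383562,0.869198119862051
190.536657534247,0.87150166747327
192.085150684932,0.883350827570323
193.633643835616,0.879134526581128
195.182136986301,0.861616719007614
196.730630136986,0.887580784778841
198.279123287671,0.881050096031956
199.827616438356,0.86529134888699
201.376109589041,0.88288718295333
202.924602739726,0.873227170823855
204.473095890411,0.879614991409299
206.021589041096,0.856174973639641
207.570082191781,0.885884364054406
209.118575342466,0.88853560456573
210.667068493151,0.881375327275775
212.215561643836,0.887815928715534
213.763068493151,0.880689592479524
215.311561643836,0.873917485958728
216.860054794521,0.879267389528025
218.408547945206,0.885586951034711
219.95704109589,0.879222934128263
221.505534246575,0.88326668148677
223.05402739726,0.894591892045037
224.602520547945,0.886893579355751
226.15101369863,0.883645297770046
227.699506849315,0.889372417436665
229.248,0.885963996835888
230.796493150685,0.888742114825847
232.34498630137,0.90221386022183
233.893479452055,0.884612324158217
235.44197260274,0.889102436162047
236.990465753425,0.877409289112691
238.53895890411,0.898279079236621
240.087452054795,0.887861460842033
241.635945205479,0.887290919186751
243.184438356164,0.88949382802843
244.732931506849,0.896836291179381
246.281424657534,0.908215686580832
247.829917808219,0.896437220802603
249.378410958904,0.900102854905387
250.926904109589,0.891616550412837
252.474410958904,0.901334401065237
254.022904109589,0.897490915086809
255.571397260274,0.902640193928631
257.119890410959,0.906120879193482
258.668383561644,0.90186284421157
260.216876712329,0.895947730507163
261.765369863014,0.911519022992973
263.313863013699,0.884858059850394
264.862356164384,0.898848876212704
266.410849315069,0.915519968556424
267.959342465753,0.896344272827099
269.507835616438,0.903373507748621
271.056328767123,0.90991484328518
272.604821917808,0.892739392382195
274.153315068493,0.893900856721578
275.701808219178,0.904289155999643
277.250301369863,0.889377836754144
278.798794520548,0.890684011269259
280.347287671233,0.90545634460836
281.895780821918,0.89845194817617
283.444273972603,0.898564971711019
284.992767123288,0.918514160626565
286.541260273973,0.88995359574638
288.089753424658,0.896586325184248
289.637260273973,0.903925333364138
291.185753424658,0.898783430235943
292.734246575343,0.910503975505121
294.282739726027,0.914459907359475
295.831232876712,0.89507968495897
297.379726027397,0.919311848309512
298.928219178082,0.906154096883708
300.476712328767,0.919192376227453
302.025205479452,0.907034020652028
303.573698630137,0.92826867615647
305.122191780822,0.909640359625314
306.670684931507,0.908069875492379
308.219178082192,0.907235169329474
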