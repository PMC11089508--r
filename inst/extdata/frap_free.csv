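"time_s","intensity_norm"
0.0767123287671233,0.182296893104798
0.232876712328767,0.242703763047051
0.386301369863014,0.276804499887323
0.53972602739726,0.306231768324975
0.695890410958904,0.340113110752185
0.849315068493151,0.368595693998523
1.0027397260274,0.389274517066991
1.15890410958904,0.410122403832231
1.31232876712329,0.419553946939895
1.46849315068493,0.443160047939341
1.62191780821918,0.450484269211639
1.77534246575343,0.468807918986073
1.93150684931507,0.489330174745564
2.08493150684932,0.503313517321703
2.24109589041096,0.511662110933702
2.39452054794521,0.514855447311618
2.54794520547945,0.533889065002498
2.7041095890411,0.54487614336066
2.85753424657534,0.557375016730812
3.01369863013699,0.561650090393984
3.16712328767123,0.580533806479164
3.32054794520548,0.584757348267036
3.47671232876712,0.597278011332478
3.63013698630137,0.608686124237454
3.78630136986301,0.617777259242741
3.93972602739726,0.628705827624149
4.09315068493151,0.619193168887338
4.24931506849315,0.642281420612888
4.4027397260274,0.645543062770952
4.55616438356165,0.647259836610539
4.71232876712329,0.653075291294716
4.86575342465754,0.665768447116171
5.02191780821918,0.664869279869625
5.17534246575343,0.681354727261938
5.32876712328767,0.682983960195484
5.48493150684932,0.681408975949155
5.63835616438356,0.697778017258425
5.79452054794521,0.695119937505824
5.94794520547945,0.700215061312738
6.1013698630137,0.717186007555211
6.25753424657534,0.709444485131855
6.41095890410959,0.723173187725034
6.56712328767123,0.722268599186232
6.72054794520548,0.723270599686869
6.87397260273973,0.725514522806677
7.03013698630137,0.73129419979094
7.18356164383562,0.734311580634266
7.33972602739726,0.728803624212873
7.49315068493151,0.730848597730643
7.64657534246576,0.747967496745713
7.8027397260274,0.742142278676624
7.95616438356165,0.753717487795834
8.10958904109589,0.759463178428727
8.26575342465754,0.75523693706158
8.41917808219178,0.765715554170528
8.57534246575343,0.761916951759401
8.72876712328767,0.766751930979567
8.88219178082192,0.753181723701661
9.03835616438356,0.777198524477879
9.19178082191781,0.771799995105324
9.34794520547945,0.784459631737824
9.5013698630137,0.78371322954314
9.65479452054795,0.785854273948009
9.81095890410959,0.777422307274287
9.96438356164384,0.785333360692138
10.1205479452055,0.797743748569714
10.2739726027397,0.788418539762247
10.427397260274,0.804345698378121
10.5835616438356,0.778581682888421
10.7369863013699,0.801117986307238
10.8931506849315,0.819308640961558
11.0465753424658,0.81603455312817
11.2,0.805771434765114
11.3561643835616,0.813132581847229
11.5095890410959,0.814303129644713
11.6630136986301,0.801807385460746
11.8191780821918,0.811625063078369
11.972602739726,0.82683481792451
12.1287671232877,0.825261578120732
12.2821917808219,0.82116266255595
12.4356164383562,0.828879662894758
12.5917808219178,0.81492330952915
12.7452054794521,0.822135103458996
12.9013698630137,0.830574388054601
13.0547945205479,0.814974377385993
13.2082191780822,0.832312815011562
13.3643835616438,0.834590152843642
13.5178082191781,0.832203338486047
13.6739726027397,0.839201842359356
13.827397260274,0.8392915193823
13.9808219178082,0.830750440353751
14.1369863013699,0.839607182975746
14.2904109589041,0.853669219946554
14.4465753424658,0.839755221685509
14.6,0.838807491535034
14.7534246575343,0.845711737722688
14.9095890410959,0.848332661094387
15.0630136986301,0.852513520268531
15.2164383561644,0.842363714507528
15.372602739726,0.847708621199872
15.5260273972603,0.844255362985917
15.6821917808219,0.838953048535943
15.8356164383562,0.85711372871475
15.9890410958904,0.856556905320075
16.1452054794521,0.85281429332986
16.2986301369863,0.857464403175208
16.4547945205479,0.866401108577837
16.6082191780822,0.861085639022881
16.7616438356164,0.854204367125274
16.9178082191781,0.855918517083668
17.0712328767123,0.860589725150696
17.227397260274,0.870554341774096
17.3808219178082,0.858495644690033
17.5342465753425,0.851617026135719
17.6904109589041,0.859601757401033
17.8438356164384,0.856859522976335
18,0.87536187998025
18.1534246575343,0.877924960404016
18.3068493150685,0.880167947667477
18.4630136986301,0.866982927617936
18.6164383561644,0.857836073907275
18.7698630136986,0.879040812747296
18.9260273972603,0.86352352205628
19.0794520547945,0.867039926327474
19.2356164383562,0.870824938048647
19.3890410958904,0.879637073474786
19.5424657534247,0.877658230700055
19.6986301369863,0.880487195065489
19.8520547945206,0.883081814891556
20.0082191780822,0.881719202778874
20.1616438356164,0.870759299978716
20.3150684931507,0.87979737042792
20.4712328767123,0.902306846467606
20.6246575342466,0.886057357647453
20.7808219178082,0.895395540422533
20.9342465753425,0.883524859480595
21.0876712328767,0.875764997613416
21.2438356164384,0.890577077370854
21.3972602739726,0.885972111964837
21.5534246575343,0.880868962667419
21.7068493150685,0.888650514473485
21.8602739726027,0.883480314637912
22.0164383561644,0.880037733886378
22.1698630136986,0.888908739769626
22.3232876712329,0.871229727257406
22.4794520547945,0.883777492707385
22.6328767123288,0.877593546579532
22.7890410958904,0.879554325679859
22.9424657534247,0.891819587597521
23.0958904109589,0.90769331435753
23.2520547945206,0.885422913486887
23.4054794520548,0.901662291611088
23.5616438356164,0.908519639789397
23.7150684931507,0.897876643665564
23.8684931506849,0.890279735187599
24.0246575342466,0.88814248920401
24.1780821917808,0.906638872330209
24.3342465753425,0.889173637458323
24.4876712328767,0.901068815445448
24.641095890411,0.889314164928441
24.7972602739726,0.889895240204779
24.9506849315069,0.886069951224431
25.1068493150685,0.906545026514409
25.2602739726027,0.892232837025073
25.413698630137,0.894854335863317
25.5698630136986,0.889160813621666
25.7232876712329,0.895744814590299
25.8767123287671,0.906079853178818
26.0328767123288,0.904100422220615
26.186301369863,0.882030150168061
26.3424657534247,0.903627851905356
26.4958904109589,0.89675534791336
26.6493150684932,0.886112027993411
26.8054794520548,0.904775241138917
26.958904109589,0.891576059952403
27.1150684931507,0.900627656424133
27.2684931506849,0.900073624646396
27.4219178082192,0.903460273554484
27.5780821917808,0.903440918169664
27.7315068493151,0.891520762291181
27.8876712328767,0.915146984919898
28.041095890411,0.905235382938888
28.1945205479452,0.905988535645984
28.3506849315069,0.899982292049149
28.5041095890411,0.906944588263537
28.6602739726027,0.909025970476067
28.813698630137,0.898975203142541
28.9671232876712,0.898048642799273
29.1232876712329,0.913867269729199
29.2767123287671,0.897036492972036
29.4301369863014,0.899396494997079
29.586301369863,0.903257978687986
29.7397260273973,0.916078079196262
29.8958904109589,0.893551349895081
30.0493150684932,0.923880655217376
30.2027397260274,0.878705703795496
30.3589041095891,0.893673633787588
30.5123287671233,0.907764079964935
30.6684931506849,0.908787902930877
30.8219178082192,0.907184045453956
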