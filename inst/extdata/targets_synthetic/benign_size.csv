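"age_bin","size_bin","value"
"15-20","0-1",0.14633521271143
"20-25","0-1",0.19185687847008
"25-30","0-1",0.201049868766404
"30-35","0-1",0.199546485260771
"35-40","0-1",0.217498968221213
"40-45","0-1",0.229992520568437
"45-50","0-1",0.237058193502321
"50-55","0-1",0.259393063583815
"55-60","0-1",0.277736411020104
"60-65","0-1",0.302001740644038
"65-70","0-1",0.329055441478439
"70-75","0-1",0.338709677419355
"75-80","0-1",0.334254143646409
"80-85","0-1",0.448123620309051
"15-20","1-2",0.267042542286007
"20-25","1-2",0.235657001850709
"25-30","1-2",0.25249343832021
"30-35","1-2",0.238095238095238
"35-40","1-2",0.244325216673545
"40-45","1-2",0.243455497382199
"45-50","1-2",0.233488039985719
"50-55","1-2",0.245303468208092
"55-60","1-2",0.223752792256143
"60-65","1-2",0.214099216710183
"65-70","1-2",0.217659137577002
"70-75","1-2",0.210322580645161
"75-80","1-2",0.202578268876611
"80-85","1-2",0.193524650478293
"15-20","2-3",0.265248590466427
"20-25","2-3",0.240592227020358
"25-30","2-3",0.233595800524934
"30-35","2-3",0.248072562358277
"35-40","2-3",0.231943871234007
"40-45","2-3",0.235602094240838
"45-50","2-3",0.237772224205641
"50-55","2-3",0.225433526011561
"55-60","2-3",0.220774385703649
"60-65","2-3",0.230635335073977
"65-70","2-3",0.200205338809035
"70-75","2-3",0.199354838709677
"75-80","2-3",0.198895027624309
"80-85","2-3",0.175128771155261
"15-20","3-4",0.166324961558175
"20-25","3-4",0.169031462060457
"25-30","3-4",0.156430446194226
"30-35","3-4",0.158730158730159
"35-40","3-4",0.155179529508873
"40-45","3-4",0.143979057591623
"45-50","3-4",0.148875401642271
"50-55","3-4",0.134393063583815
"55-60","3-4",0.14668652271035
"60-65","3-4",0.123150565709312
"65-70","3-4",0.121149897330595
"70-75","3-4",0.129677419354839
"75-80","3-4",0.142725598526703
"80-85","3-4",0.0816777041942605
"15-20","4-5",0.0766273705791902
"20-25","4-5",0.0857495373226403
"25-30","4-5",0.0824146981627297
"30-35","4-5",0.0866213151927438
"35-40","4-5",0.0825423029302517
"40-45","4-5",0.0822737471952132
"45-50","4-5",0.0710460549803642
"50-55","4-5",0.0690028901734104
"55-60","4-5",0.0685033507073716
"60-65","4-5",0.066579634464752
"65-70","4-5",0.0754620123203285
"70-75","4-5",0.0651612903225806
"75-80","4-5",0.074585635359116
"80-85","4-5",0.0559234731420162
"15-20","5-6",0.035366478728857
"20-25","5-6",0.0444170265268353
"25-30","5-6",0.0383202099737533
"30-35","5-6",0.0403628117913832
"35-40","5-6",0.0392075938918696
"40-45","5-6",0.0362752430815258
"45-50","5-6",0.0367725812209925
"50-55","5-6",0.0382947976878613
"55-60","5-6",0.0335070737155622
"60-65","5-6",0.0365535248041775
"65-70","5-6",0.0349075975359343
"70-75","5-6",0.032258064516129
"75-80","5-6",0.0276243093922652
"80-85","5-6",0.022075055187638
"15-20","6+",0.0430548436699129
"20-25","6+",0.0326958667489204
"25-30","6+",0.0356955380577428
"30-35","6+",0.0285714285714286
"35-40","6+",0.0293025175402394
"40-45","6+",0.0284218399401645
"45-50","6+",0.0349875044626919
"50-55","6+",0.0281791907514451
"55-60","6+",0.0290394638868206
"60-65","6+",0.0269799825935596
"65-70","6+",0.0215605749486653
"70-75","6+",0.0245161290322581
"75-80","6+",0.0193370165745856
"80-85","6+",0.0235467255334805
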