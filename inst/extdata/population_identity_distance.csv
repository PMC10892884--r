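pop1,pop2,identity,distance
Kunming,Qujing,0.8993,0.1062
Kunming,Lincang,0.8074,0.2139
Kunming,Puer,0.8198,0.1987
Kunming,Baoshan,0.8882,0.1186
Kunming,Honghe,0.8359,0.1792
Kunming,Xishuangbanna,0.8456,0.1677
Kunming,Dali,0.8621,0.1484
Qujing,Lincang,0.8949,0.1111
Qujing,Puer,0.8883,0.1184
Qujing,Baoshan,0.9245,0.0785
Qujing,Honghe,0.8998,0.1056
Qujing,Xishuangbanna,0.8762,0.1321
Qujing,Dali,0.9179,0.0856
Lincang,Puer,0.8023,0.2203
Lincang,Baoshan,0.8351,0.1802
Lincang,Honghe,0.8104,0.2103
Lincang,Xishuangbanna,0.8205,0.1979
Lincang,Dali,0.8135,0.2065
Puer,Baoshan,0.8535,0.1584
Puer,Honghe,0.8210,0.1972
Puer,Xishuangbanna,0.8415,0.1725
Puer,Dali,0.8354,0.1798
Baoshan,Honghe,0.8262,0.1909
Baoshan,Xishuangbanna,0.8686,0.1409
Baoshan,Dali,0.9242,0.0788
Honghe,Xishuangbanna,0.7821,0.2458
Honghe,Dali,0.9004,0.1050
Xishuangbanna,Dali,0.8443,0.1692
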