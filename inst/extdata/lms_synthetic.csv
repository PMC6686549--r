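"sex","age","L","M","S"
"female",24,-2,16.122,0.08
"female",25,-1.993,16.06875,0.08028
"female",26,-1.986,16.017,0.08056
"female",27,-1.979,15.96675,0.08084
"female",28,-1.972,15.918,0.08112
"female",29,-1.965,15.87075,0.0814
"female",30,-1.958,15.825,0.08168
"female",31,-1.951,15.78075,0.08196
"female",32,-1.944,15.738,0.08224
"female",33,-1.937,15.69675,0.08252
"female",34,-1.93,15.657,0.0828
"female",35,-1.923,15.61875,0.08308
"female",36,-1.916,15.582,0.08336
"female",37,-1.909,15.54675,0.08364
"female",38,-1.902,15.513,0.08392
"female",39,-1.895,15.48075,0.0842
"female",40,-1.888,15.45,0.08448
"female",41,-1.881,15.42075,0.08476
"female",42,-1.874,15.393,0.08504
"female",43,-1.867,15.36675,0.08532
"female",44,-1.86,15.342,0.0856
"female",45,-1.853,15.31875,0.08588
"female",46,-1.846,15.297,0.08616
"female",47,-1.839,15.27675,0.08644
"female",48,-1.832,15.258,0.08672
"female",49,-1.825,15.24075,0.087
"female",50,-1.818,15.225,0.08728
"female",51,-1.811,15.21075,0.08756
"female",52,-1.804,15.198,0.08784
"female",53,-1.797,15.18675,0.08812
"female",54,-1.79,15.177,0.0884
"female",55,-1.783,15.16875,0.08868
"female",56,-1.776,15.162,0.08896
"female",57,-1.769,15.15675,0.08924
"female",58,-1.762,15.153,0.08952
"female",59,-1.755,15.15075,0.0898
"female",60,-1.748,15.15,0.09008
"female",61,-1.741,15.15075,0.09036
"female",62,-1.734,15.153,0.09064
"female",63,-1.727,15.15675,0.09092
"female",64,-1.72,15.162,0.0912
"female",65,-1.713,15.16875,0.09148
"female",66,-1.706,15.177,0.09176
"female",67,-1.699,15.18675,0.09204
"female",68,-1.692,15.198,0.09232
"female",69,-1.685,15.21075,0.0926
"female",70,-1.678,15.225,0.09288
"female",71,-1.671,15.24075,0.09316
"female",72,-1.664,15.258,0.09344
"male",24,-2.2,16.2072,0.075
"male",25,-2.192,16.1575,0.0753
"male",26,-2.184,16.1092,0.0756
"male",27,-2.176,16.0623,0.0759
"male",28,-2.168,16.0168,0.0762
"male",29,-2.16,15.9727,0.0765
"male",30,-2.152,15.93,0.0768
"male",31,-2.144,15.8887,0.0771
"male",32,-2.136,15.8488,0.0774
"male",33,-2.128,15.8103,0.0777
"male",34,-2.12,15.7732,0.078
"male",35,-2.112,15.7375,0.0783
"male",36,-2.104,15.7032,0.0786
"male",37,-2.096,15.6703,0.0789
"male",38,-2.088,15.6388,0.0792
"male",39,-2.08,15.6087,0.0795
"male",40,-2.072,15.58,0.0798
"male",41,-2.064,15.5527,0.0801
"male",42,-2.056,15.5268,0.0804
"male",43,-2.048,15.5023,0.0807
"male",44,-2.04,15.4792,0.081
"male",45,-2.032,15.4575,0.0813
"male",46,-2.024,15.4372,0.0816
"male",47,-2.016,15.4183,0.0819
"male",48,-2.008,15.4008,0.0822
"male",49,-2,15.3847,0.0825
"male",50,-1.992,15.37,0.0828
"male",51,-1.984,15.3567,0.0831
"male",52,-1.976,15.3448,0.0834
"male",53,-1.968,15.3343,0.0837
"male",54,-1.96,15.3252,0.084
"male",55,-1.952,15.3175,0.0843
"male",56,-1.944,15.3112,0.0846
"male",57,-1.936,15.3063,0.0849
"male",58,-1.928,15.3028,0.0852
"male",59,-1.92,15.3007,0.0855
"male",60,-1.912,15.3,0.0858
"male",61,-1.904,15.3007,0.0861
"male",62,-1.896,15.3028,0.0864
"male",63,-1.888,15.3063,0.0867
"male",64,-1.88,15.3112,0.087
"male",65,-1.872,15.3175,0.0873
"male",66,-1.864,15.3252,0.0876
"male",67,-1.856,15.3343,0.0879
"male",68,-1.848,15.3448,0.0882
"male",69,-1.84,15.3567,0.0885
"male",70,-1.832,15.37,0.0888
"male",71,-1.824,15.3847,0.0891
"male",72,-1.816,15.4008,0.0894
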