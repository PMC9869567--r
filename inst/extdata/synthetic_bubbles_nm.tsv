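length_nm
5.891
4.896
1.981
3
4.888
1.176
4.264
7.027
2.768
5.066
1.042
5.843
2.618
6.94
2.077
3.498
4.816
1.008
3.225
1.121
3.391
3.404
2.628
1.43
3.887
2.299
3.875
1.981
1.038
5.212
7.377
2.228
6.118
1.113
5.103
3.981
2.473
4.34
6.284
4.128
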