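value_nm
1.524
1.204
1.448
1.403
1.287
0.917
1.273
1.216
1.443
1.325
1.338
1.274
1.376
1.375
0.911
1.689
1.543
1.464
1.259
1.558
1.354
1.387
1.142
1.713
1.43
1.802
1.766
1.432
1.549
1.765
1.314
1.453
1.369
1.487
1.456
1.653
1.539
1.242
1.535
1.255
1.189
1.576
1.179
1.481
1.253
1.704
1.562
1.34
1.58
1.505
1.186
1.379
1.234
1.51
1.291
1.374
1.173
1.228
1.447
1.22
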