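locus,allele,frequency
D3S1358,14,0.0467
D3S1358,15,0.3341
D3S1358,16,0.3248
D3S1358,17,0.2220
D3S1358,18,0.0607
D3S1358,19,0.0093
D3S1358,20,0.0023
FGA,16,0.0023
FGA,18,0.0140
FGA,19,0.0607
FGA,20,0.0491
FGA,20.2,0.0023
FGA,21,0.0864
FGA,21.2,0.0047
FGA,22,0.1379
FGA,23,0.2593
FGA,23.2,0.0070
FGA,24,0.1776
FGA,24.2,0.0164
FGA,25,0.1168
FGA,25.2,0.0047
FGA,26,0.0491
FGA,27,0.0117
D21S11,16,0.0047
D21S11,28,0.0607
D21S11,28.2,0.0140
D21S11,29,0.2336
D21S11,30,0.2570
D21S11,30.2,0.0164
D21S11,30.3,0.0047
D21S11,31,0.0981
D21S11,31.2,0.0911
D21S11,31.3,0.0023
D21S11,32,0.0304
D21S11,32.2,0.1308
D21S11,33,0.0023
D21S11,33.2,0.0467
D21S11,34.2,0.0047
D21S11,35.2,0.0023
D19S433,11,0.0023
D19S433,12,0.0491
D19S433,12.2,0.0070
D19S433,13,0.2921
D19S433,13.2,0.0304
D19S433,14,0.2360
D19S433,14.2,0.1215
D19S433,15,0.0607
D19S433,15.2,0.1472
D19S433,16,0.0093
D19S433,16.2,0.0397
D19S433,17,0.0023
D19S433,17.2,0.0023
D18S51,10,0.0023
D18S51,12,0.0467
D18S51,13,0.2009
D18S51,14,0.1939
D18S51,15,0.1706
D18S51,16,0.1145
D18S51,17,0.0935
D18S51,18,0.0374
D18S51,19,0.0584
D18S51,20,0.0444
D18S51,21,0.0117
D18S51,22,0.0117
D18S51,23,0.0023
D18S51,24,0.0070
D18S51,25,0.0047
D2S1338,16,0.0187
D2S1338,17,0.0841
D2S1338,18,0.0771
D2S1338,19,0.1916
D2S1338,20,0.1192
D2S1338,21,0.0164
D2S1338,22,0.0514
D2S1338,23,0.2033
D2S1338,24,0.1706
D2S1338,25,0.0584
D2S1338,26,0.0070
D2S1338,27,0.0023
D5S818,7,0.0304
D5S818,9,0.0701
D5S818,10,0.2126
D5S818,11,0.3014
D5S818,12,0.2243
D5S818,13,0.1472
D5S818,14,0.0117
D5S818,15,0.0023
D13S317,8,0.2570
D13S317,9,0.1449
D13S317,10,0.1262
D13S317,11,0.2453
D13S317,12,0.1729
D13S317,13,0.0537
D7S820,7,0.0047
D7S820,8,0.1449
D7S820,9,0.0701
D7S820,9.1,0.0047
D7S820,10,0.1659
D7S820,10.1,0.0047
D7S820,11,0.3107
D7S820,12,0.2430
D7S820,13,0.0467
D7S820,14,0.0047
D16S539,8,0.0093
D16S539,9,0.2407
D16S539,10,0.1449
D16S539,11,0.2617
D16S539,12,0.1963
D16S539,13,0.1238
D16S539,14,0.0210
D16S539,15,0.0023
vWA,14,0.2360
vWA,15,0.0164
vWA,16,0.1799
vWA,17,0.2523
vWA,18,0.1729
vWA,19,0.1308
vWA,20,0.0093
vWA,21,0.0023
D8S1179,8,0.0023
D8S1179,9,0.0023
D8S1179,10,0.1168
D8S1179,11,0.1005
D8S1179,12,0.0888
D8S1179,13,0.2196
D8S1179,14,0.1846
D8S1179,15,0.1519
D8S1179,16,0.1121
D8S1179,17,0.0187
D8S1179,18,0.0023
CSF1PO,7,0.0070
CSF1PO,9,0.0374
CSF1PO,10,0.2547
CSF1PO,11,0.1963
CSF1PO,12,0.4065
CSF1PO,13,0.0771
CSF1PO,14,0.0117
CSF1PO,15,0.0047
CSF1PO,23,0.0047
TH01,6,0.1075
TH01,7,0.2570
TH01,8,0.0444
TH01,9,0.5070
TH01,9.3,0.0444
TH01,10,0.0397
TPOX,8,0.5210
TPOX,9,0.1192
TPOX,10,0.0234
TPOX,11,0.3154
TPOX,12,0.0210
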