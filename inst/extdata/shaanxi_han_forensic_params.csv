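locus,MP,PD,PIC,PE,TPI,Ho,He,P_hwe
D3S1358,0.1284,0.8716,0.6795,0.5058,1.9815,0.7477,0.7311,0.5469
D13S317,0.0762,0.9238,0.7753,0.6593,2.9722,0.8318,0.8079,0.3396
D7S820,0.0814,0.9186,0.7581,0.6060,2.5476,0.8037,0.7924,0.6354
D16S539,0.0742,0.9258,0.7677,0.6413,2.8158,0.8224,0.8020,0.4141
D19S433,0.0617,0.9383,0.7903,0.6235,2.6750,0.8131,0.8177,0.9201
TPOX,0.2056,0.7944,0.5485,0.2999,1.2738,0.6075,0.6167,0.8143
TH01,0.1652,0.8348,0.6147,0.3808,1.5070,0.6682,0.6629,0.8320
D2S1338,0.0377,0.9623,0.8432,0.6593,2.9722,0.8318,0.8630,0.2174
CSF1PO,0.1197,0.8803,0.6805,0.4593,1.7833,0.7196,0.7272,0.8481
vWA,0.0717,0.9283,0.7706,0.6060,2.5476,0.8037,0.8047,0.9718
D5S818,0.0812,0.9188,0.7535,0.5973,2.4884,0.7991,0.7897,0.6879
FGA,0.0413,0.9587,0.8361,0.6147,2.6098,0.8084,0.8559,0.0597
D8S1179,0.0426,0.9574,0.8321,0.6774,3.1471,0.8411,0.8541,0.6524
D21S11,0.0494,0.9506,0.8182,0.6683,3.0571,0.8364,0.8409,0.9216
D18S51,0.0401,0.9599,0.8468,0.6774,3.1471,0.8411,0.8658,0.3338
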