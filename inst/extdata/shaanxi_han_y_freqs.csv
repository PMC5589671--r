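locus,allele,frequency
DYS635,19,0.1389
DYS635,20,0.2778
DYS635,21,0.2778
DYS635,22,0.2037
DYS635,23,0.0556
DYS635,24,0.0370
DYS635,25,0.0093
DYS456,13,0.0093
DYS456,14,0.2685
DYS456,15,0.4815
DYS456,16,0.1574
DYS456,17,0.0741
DYS456,18,0.0093
DYS458,13,0.0093
DYS458,14,0.0185
DYS458,15,0.1296
DYS458,15.2,0.0093
DYS458,16,0.1852
DYS458,17,0.2778
DYS458,18,0.2222
DYS458,19,0.1111
DYS458,20,0.0185
DYS458,21,0.0093
DYS458,22,0.0093
DYS391,9,0.0185
DYS391,10,0.7407
DYS391,11,0.2315
DYS391,12,0.0093
DYS392,10,0.0093
DYS392,11,0.1481
DYS392,12,0.1481
DYS392,13,0.3519
DYS392,14,0.2685
DYS392,15,0.0741
DYS390,20,0.0093
DYS390,22,0.0093
DYS390,23,0.5093
DYS390,24,0.2407
DYS390,25,0.2222
DYS390,26,0.0093
DYS393,12,0.5556
DYS393,13,0.2593
DYS393,14,0.1111
DYS393,15,0.0741
DYS438,8,0.0185
DYS438,10,0.7593
DYS438,11,0.2130
DYS438,12,0.0093
DYS385ab,"10,12",0.0093
DYS385ab,"10,17",0.0185
DYS385ab,"11,11",0.0370
DYS385ab,"11,12",0.0278
DYS385ab,"11,13",0.0093
DYS385ab,"11,16",0.0185
DYS385ab,"11,17",0.0370
DYS385ab,"11,18",0.0093
DYS385ab,"11,19",0.0370
DYS385ab,"12,12",0.0370
DYS385ab,"12,14",0.0093
DYS385ab,"12,15",0.0093
DYS385ab,"12,16",0.0741
DYS385ab,"12,17",0.0185
DYS385ab,"12,19",0.0926
DYS385ab,"12,20",0.0741
DYS385ab,"13,13",0.1204
DYS385ab,"13,14",0.0370
DYS385ab,"13,15",0.0093
DYS385ab,"13,16",0.0278
DYS385ab,"13,17",0.0093
DYS385ab,"13,18",0.0926
DYS385ab,"13,19",0.0278
DYS385ab,"13,20",0.0093
DYS385ab,"13,21",0.0278
DYS385ab,"13,26",0.0093
DYS385ab,"14,17",0.0185
DYS385ab,"14,18",0.0185
DYS385ab,"14,19",0.0093
DYS385ab,"14,21",0.0093
DYS385ab,"14,22",0.0093
DYS385ab,"15,17",0.0093
DYS385ab,"15,19",0.0093
DYS385ab,"15,20",0.0093
DYS385ab,"15,22",0.0093
DYS385ab,"18,19",0.0093
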