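locus,gd
DYS635,0.7876
DYS456,0.6719
DYS458,0.8165
DYS391,0.4010
DYS392,0.7617
DYS390,0.6390
DYS393,0.6120
DYS438,0.3813
DYS385ab,0.9983
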