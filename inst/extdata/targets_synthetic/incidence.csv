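"age_bin","value"
"15-20",0.000572532741716167
"20-25",0.000733478651638963
"25-30",0.00103945760162134
"30-35",0.00112286946112859
"35-40",0.00150225338007011
"40-45",0.00176846313962621
"45-50",0.00208268835664631
"50-55",0.00220955385570047
"55-60",0.00272837327519228
"60-65",0.00254063756098794
"65-70",0.00268490784964516
"70-75",0.00271717059844206
"75-80",0.00258622875446885
"80-85",0.00368755243886017
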