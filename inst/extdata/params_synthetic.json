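{"schema":"thyronod_param_set_v1","age_bins":["15-20","20-25","25-30","30-35","35-40","40-45","45-50","50-55","55-60","60-65","65-70","70-75","75-80","80-85"],"dev_rate":[0.0118,0.014159999999999999,0.01652,0.018880000000000001,0.021239999999999998,0.021239999999999998,0.021239999999999998,0.018880000000000001,0.01652,0.014159999999999999,0.0118,0.0094400000000000005,0.0070799999999999995,0.0058999999999999999],"malig_growth_logmu":[-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971,-0.22314355131420971],"malig_growth_logsigma":[0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5,0.5],"ben_growth_logmu":[0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511,0.91629073187415511],"ben_growth_logsigma":[0.25,0.25,0.25,0.25,0.25,0.25,0.25,0.25,0.25,0.25,0.25,0.25,0.25,0.25],"B1":[0.00050000000000000001,0.00069999999999999999,0.001,0.0012999999999999999,0.0016000000000000001,0.0019,0.0022000000000000001,0.0023999999999999998,0.0023999999999999998,0.0022000000000000001,0.0019,0.0016000000000000001,0.0014,0.0011999999999999999],"B2":[0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001,0.00020000000000000001]}
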