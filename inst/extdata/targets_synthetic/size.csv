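"age_bin","size_bin","value"
"15-20","0-1",0.0535714285714286
"20-25","0-1",0.0633802816901408
"25-30","0-1",0.150753768844221
"30-35","0-1",0.113207547169811
"35-40","0-1",0.136200716845878
"40-45","0-1",0.177018633540373
"45-50","0-1",0.116216216216216
"50-55","0-1",0.144356955380577
"55-60","0-1",0.145695364238411
"60-65","0-1",0.191542288557214
"65-70","0-1",0.135678391959799
"70-75","0-1",0.122282608695652
"75-80","0-1",0.137254901960784
"80-85","0-1",0.146067415730337
"15-20","1-2",0.267857142857143
"20-25","1-2",0.394366197183099
"25-30","1-2",0.396984924623116
"30-35","1-2",0.471698113207547
"35-40","1-2",0.491039426523298
"40-45","1-2",0.481366459627329
"45-50","1-2",0.494594594594595
"50-55","1-2",0.496062992125984
"55-60","1-2",0.39514348785872
"60-65","1-2",0.465174129353234
"65-70","1-2",0.492462311557789
"70-75","1-2",0.497282608695652
"75-80","1-2",0.555555555555556
"80-85","1-2",0.514044943820225
"15-20","2-3",0.383928571428571
"20-25","2-3",0.352112676056338
"25-30","2-3",0.306532663316583
"30-35","2-3",0.334905660377358
"35-40","2-3",0.254480286738351
"40-45","2-3",0.254658385093168
"45-50","2-3",0.294594594594595
"50-55","2-3",0.26246719160105
"55-60","2-3",0.364238410596026
"60-65","2-3",0.271144278606965
"65-70","2-3",0.271356783919598
"70-75","2-3",0.301630434782609
"75-80","2-3",0.264705882352941
"80-85","2-3",0.292134831460674
"15-20","3-4",0.232142857142857
"20-25","3-4",0.140845070422535
"25-30","3-4",0.115577889447236
"30-35","3-4",0.0660377358490566
"35-40","3-4",0.0931899641577061
"40-45","3-4",0.0683229813664596
"45-50","3-4",0.0891891891891892
"50-55","3-4",0.057742782152231
"55-60","3-4",0.0728476821192053
"60-65","3-4",0.0597014925373134
"65-70","3-4",0.0778894472361809
"70-75","3-4",0.0597826086956522
"75-80","3-4",0.0326797385620915
"80-85","3-4",0.0393258426966292
"15-20","4-5",0.0535714285714286
"20-25","4-5",0.0352112676056338
"25-30","4-5",0.0301507537688442
"30-35","4-5",0.00943396226415094
"35-40","4-5",0.021505376344086
"40-45","4-5",0.0062111801242236
"45-50","4-5",0
"50-55","4-5",0.031496062992126
"55-60","4-5",0.0198675496688742
"60-65","4-5",0.00995024875621891
"65-70","4-5",0.0201005025125628
"70-75","4-5",0.016304347826087
"75-80","4-5",0.0065359477124183
"80-85","4-5",0.00842696629213483
"15-20","5-6",0
"20-25","5-6",0.0140845070422535
"25-30","5-6",0
"30-35","5-6",0.00471698113207547
"35-40","5-6",0.003584229390681
"40-45","5-6",0.0062111801242236
"45-50","5-6",0
"50-55","5-6",0.005249343832021
"55-60","5-6",0
"60-65","5-6",0
"65-70","5-6",0.00251256281407035
"70-75","5-6",0
"75-80","5-6",0
"80-85","5-6",0
"15-20","6+",0.00892857142857143
"20-25","6+",0
"25-30","6+",0
"30-35","6+",0
"35-40","6+",0
"40-45","6+",0.0062111801242236
"45-50","6+",0.00540540540540541
"50-55","6+",0.0026246719160105
"55-60","6+",0.0022075055187638
"60-65","6+",0.00248756218905473
"65-70","6+",0
"70-75","6+",0.00271739130434783
"75-80","6+",0.00326797385620915
"80-85","6+",0
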