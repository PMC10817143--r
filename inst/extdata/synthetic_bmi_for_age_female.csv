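# indicator: bmi_for_age_synthetic
# sex: female
# age_unit: years
age,L,M,S
10,-1.2,15.8,0.105
10.5,-1.21,16.11,0.1055
11,-1.22,16.41,0.106
11.5,-1.23,16.7,0.1065
12,-1.24,16.99,0.107
12.5,-1.25,17.28,0.1075
13,-1.26,17.55,0.108
13.5,-1.27,17.82,0.1085
14,-1.28,18.09,0.109
14.5,-1.29,18.35,0.1095
15,-1.3,18.6,0.11
15.5,-1.31,18.85,0.1105
16,-1.32,19.09,0.111
16.5,-1.33,19.32,0.1115
17,-1.34,19.55,0.112
17.5,-1.35,19.78,0.1125
18,-1.36,19.99,0.113
18.5,-1.37,20.2,0.1135
19,-1.38,20.41,0.114
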