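# indicator: height_for_age_synthetic
# sex: female
# age_unit: years
age,L,M,S
10,1,152.84,0.0452
10.5,1,154.88,0.0448
11,1,156.52,0.0444
11.5,1,157.82,0.044
12,1,158.87,0.0436
12.5,1,159.7,0.0432
13,1,160.37,0.0428
13.5,1,160.9,0.0424
14,1,161.32,0.042
14.5,1,161.66,0.0416
15,1,161.93,0.0412
15.5,1,162.14,0.0408
16,1,162.32,0.0404
16.5,1,162.45,0.04
17,1,162.56,0.0396
17.5,1,162.65,0.0392
18,1,162.72,0.0388
18.5,1,162.78,0.0384
19,1,162.82,0.038
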