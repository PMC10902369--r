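parameter,animal_1,animal_2,animal_3,animal_4,animal_5,animal_6,printed_mean,printed_sd
weight_kg,31,32,28,28,31,32,30,1.6
heart_rate_bpm,134,80,87,81,95,120,100,20.4
fio2_pct,90,77,88,75,89,88,84.5,6.1
pao2_kpa,28.6,26.4,15.6,23.9,10.3,20.6,20.9,6.3
paco2_kpa,8.0,7.1,6.3,6.7,7.1,7.9,7.2,0.6
pf_ratio_mmhg,268,248,156,239,87,176,196,63
ph,7.24,7.35,7.36,7.34,7.29,7.18,7.30,0.07
cardiac_output_l_min,4.0,3.2,3.2,2.9,3.7,3.1,3.4,0.4
sao2_pct,98.1,98.3,97.0,99.9,98.3,98.2,98.3,0.8
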