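variable,single_mean,single_sd,single_n,combination_mean,combination_sd,combination_n,total_mean,total_sd
age_days,830.49,534.18,152017,848.83,517.23,54842,835.35,529.80
baseline_temp_c,38.59,0.53,152017,38.76,0.56,54842,38.63,0.54
max_temp_c,38.98,0.67,152017,39.29,0.58,54842,39.09,0.65
fever_duration_h,25.08,17.38,152017,28.81,16.40,54842,26.02,17.22
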