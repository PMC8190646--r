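threshold_c,horizon_h,single_mean,single_sd,combination_mean,combination_sd,total_mean_printed,total_sd_printed
38,6,-3.99,2.87,-2.86,2.39,-3.69,2.79
38,8,-5.21,3.79,-4.15,3.30,-4.92,3.70
38,10,-6.42,4.62,-5.41,4.21,-6.15,4.54
38,12,-7.68,5.47,-6.64,5.13,-7.40,5.40
39,6,-5.54,3.29,-4.31,2.64,-5.11,3.14
39,8,-7.40,4.33,-6.23,3.61,-6.99,4.13
39,10,-9.31,5.27,-8.11,4.58,-8.89,5.07
39,12,-11.33,6.24,-10.00,5.55,-10.86,6.04
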