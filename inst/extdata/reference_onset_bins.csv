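onset_bin,single_n,combination_n
<37,328,49
"[37,38)",8905,2079
"[38,39)",106781,33379
"[39,40)",33856,17818
>=40,2147,1517
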