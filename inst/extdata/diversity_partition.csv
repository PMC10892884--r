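statistic,value
mean_HT,0.2962
sd_HT,0.0189
mean_HS,0.1931
sd_HS,0.0073
GST,0.3482
Nm,0.9360
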