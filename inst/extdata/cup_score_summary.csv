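temperature_C,cup_score_mean,cup_score_sd,n_points
30,83.2,1.66,18
40,83.5,1.45,18
50,83.6,0.88,18
60,83.26,1.71,18
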